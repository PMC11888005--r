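local_store <- function() {
  session_store(withr::local_tempfile(fileext = ".jsonl",
                                      .local_envir = parent.frame()))
}

test_that("append then fetch returns an equal record", {
  store <- local_store()
  rec <- append_record_for(store, make_patient(), record_id = "r1")
  fetched <- fetch_session(store, "r1")
  expect_equal(fetched$graded_items, rec$graded_items)
  expect_identical(fetched$record_id, rec$record_id)
  expect_identical(fetched$technician_name, rec$technician_name)
  expect_equal(fetched$score, rec$score)
  expect_length(fetched$event_log, length(rec$event_log))
})

test_that("duplicate record ids and unwritable stores are errors", {
  store <- local_store()
  append_record_for(store, make_patient(), record_id = "dup")
  expect_error(
    append_record_for(store, make_patient(), seed = 2, record_id = "dup"),
    "duplicate", class = "hss_store_error"
  )
  ro <- session_store(file.path(withr::local_tempdir(), "no", "such", "dir",
                                "sessions.jsonl"))
  expect_error(append_record_for(ro, make_patient(), record_id = "x"),
               class = "hss_store_error")
})

test_that("student history filters, orders chronologically and keeps scores", {
  store <- local_store()
  truth <- derive_ground_truth(make_patient())
  wrong1 <- notes_from_truth(truth); wrong1$audiometry_left <- "refer"
  append_record_for(store, make_patient(), seed = 1, technician = "A",
                    record_id = "a1")
  append_record_for(store, make_patient(), seed = 2, technician = "A",
                    notes = wrong1, record_id = "a2")
  append_record_for(store, make_patient(), seed = 3, technician = "A",
                    record_id = "a3")
  append_record_for(store, make_patient(), seed = 4, technician = "B",
                    record_id = "b1")
  append_record_for(store, make_patient(), seed = 5, technician = "B",
                    record_id = "b2")

  ha <- student_history(store, "A")
  expect_identical(nrow(ha), 3L)
  expect_identical(ha$record_id, c("a1", "a2", "a3"))
  expect_equal(ha$score, c(1.0, 6 / 7, 1.0))
  expect_identical(nrow(student_history(store, "B")), 2L)
  expect_identical(nrow(student_history(store, "nobody")), 0L)
})

test_that("records are immutable: appending never rewrites earlier lines", {
  store <- local_store()
  append_record_for(store, make_patient(), record_id = "first")
  line1 <- readLines(store$path)[1]
  append_record_for(store, make_patient(), seed = 2, record_id = "second")
  lines <- readLines(store$path)
  expect_identical(lines[1], line1)
  expect_length(lines, 2)
})

test_that("cohort summary matches a brute-force recount over planted errors", {
  store <- local_store()
  base <- make_patient()
  truth <- derive_ground_truth(base)
  # plant a known error pattern across 10 records
  planted <- list()
  for (i in 1:10) {
    notes <- notes_from_truth(truth)
    if (i <= 3) notes$otoscopy_left <- "abnormal"       # 3 wrong
    if (i <= 5) notes$final_recommendation <- "refer_both"  # 5 wrong
    planted[[i]] <- notes
    append_record_for(store, base, seed = i,
                      technician = paste0("S", (i %% 3) + 1),
                      notes = notes, record_id = sprintf("r%02d", i))
  }
  summary <- cohort_summary(store)

  # brute-force oracle: recount from the planted notes themselves
  correct <- as_tibble(truth)$correct_answer
  items <- as_tibble(truth)$item
  planted_rates <- vapply(seq_along(items), function(j) {
    mean(vapply(planted, function(n) {
      !identical(n[[items[j]]], correct[j])
    }, logical(1)))
  }, numeric(1))
  expect_equal(summary$item_error_rates$error_rate, planted_rates)
  expect_equal(summary$item_error_rates$error_rate[items == "otoscopy_left"],
               0.3)
  expect_equal(
    summary$item_error_rates$error_rate[items == "final_recommendation"], 0.5
  )
  planted_scores <- vapply(planted, function(n) {
    grade_session(n, truth)$score
  }, numeric(1))
  expect_equal(summary$mean_score, mean(planted_scores))
  expect_identical(summary$n_sessions, 10L)
  expect_identical(summary$n_students, 3L)
  expect_identical(summary$sessions_per_patient$n_sessions, 10L)
})

test_that("a singleton cohort equals that record's own statistics", {
  store <- local_store()
  truth <- derive_ground_truth(make_patient())
  notes <- notes_from_truth(truth)
  notes$tympanometry_right <- "abnormal"
  append_record_for(store, make_patient(), notes = notes, record_id = "only")
  summary <- cohort_summary(store)
  expect_equal(summary$mean_score, 6 / 7)
  expect_equal(summary$item_error_rates$error_rate,
               as.numeric(summary$item_error_rates$item == "tympanometry_right"))
})

test_that("an empty store cannot be summarised but yields empty histories", {
  missing <- session_store(file.path(withr::local_tempdir(), "none.jsonl"))
  expect_error(cohort_summary(missing), class = "hss_store_error")
  empty_path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), empty_path)
  empty <- session_store(empty_path)
  expect_error(cohort_summary(empty), "empty", class = "hss_store_error")
  expect_identical(nrow(student_history(empty, "A")), 0L)
})

test_that("cohort summaries export to CSV and plot", {
  store <- local_store()
  append_record_for(store, make_patient(), record_id = "c1")
  append_record_for(store, make_patient(), seed = 2, technician = "S2",
                    record_id = "c2")
  summary <- cohort_summary(store)
  csv <- withr::local_tempfile(fileext = ".csv")
  export_cohort(summary, csv)
  back <- utils::read.csv(csv)
  expect_identical(names(back), c("metric", "group", "value"))
  expect_equal(back$value[back$metric == "mean_score"], summary$mean_score)
  expect_identical(sum(back$metric == "item_error_rate"), 7L)
  p <- autoplot(summary)
  expect_s3_class(p, "ggplot")
  expect_identical(nrow(tidy(summary)), 7L)
  expect_identical(glance(summary)$n_sessions, 2L)
})
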
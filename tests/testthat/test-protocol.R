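# Independent rule-table oracle for tympanogram classification, written
# directly from the screening typology rather than via the package's code
# path.
oracle_tymp <- function(peak_present, pressure, compliance, ecv, band, norms) {
  type <- "A"
  if (!peak_present) {
    type <- "B"
  } else if (pressure < norms$peak_pressure[1]) {
    type <- "C"
  } else if (compliance < norms$static_compliance[1]) {
    type <- "As"
  } else if (compliance > norms$static_compliance[2]) {
    type <- "Ad"
  }
  ecv_range <- norms$ecv[[band]]
  abnormal <- type %in% c("B", "C") ||
    ecv < ecv_range[1] || ecv > ecv_range[2]
  list(type = type, result = if (abnormal) "abnormal" else "normal")
}

test_that("tympanogram classification matches the worked screening examples", {
  norms <- normative_ranges()
  a <- classify_tympanogram(
    tympanogram_profile(TRUE, peak_pressure = -50, static_compliance = 0.8,
                        ear_canal_volume = 1.2),
    "adult", norms
  )
  expect_identical(a, list(type = "A", result = "normal"))

  b <- classify_tympanogram(
    tympanogram_profile(FALSE, ear_canal_volume = 3.0), "adult", norms
  )
  expect_identical(b, list(type = "B", result = "abnormal"))

  c <- classify_tympanogram(
    tympanogram_profile(TRUE, peak_pressure = -250, static_compliance = 0.5,
                        ear_canal_volume = 1.2),
    "adult", norms
  )
  expect_identical(c, list(type = "C", result = "abnormal"))
})

test_that("tympanogram classification agrees with the rule table over a dense grid", {
  norms <- normative_ranges()
  grid <- expand.grid(
    peak_present = c(TRUE, FALSE),
    pressure = seq(-400, 200, by = 50),
    compliance = seq(0, 2.4, by = 0.2),
    ecv = seq(0.2, 3.2, by = 0.3),
    band = c("child", "adult"),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    profile <- if (g$peak_present) {
      tympanogram_profile(TRUE, peak_pressure = g$pressure,
                          static_compliance = g$compliance,
                          ear_canal_volume = g$ecv)
    } else {
      tympanogram_profile(FALSE, ear_canal_volume = g$ecv)
    }
    got <- classify_tympanogram(profile, g$band, norms)
    want <- oracle_tymp(g$peak_present, g$pressure, g$compliance, g$ecv,
                        g$band, norms)
    expect_identical(got, want)
  }
})

test_that("recommend reproduces the full 2x2 referral table (oracle enumeration)", {
  # oracle: enumerate the flag table directly
  oracle <- function(medical, audiologic) {
    if (medical && audiologic) "refer_both"
    else if (medical) "refer_physician"
    else if (audiologic) "refer_audiologist"
    else "pass"
  }
  for (medical in c(FALSE, TRUE)) {
    for (audiologic in c(FALSE, TRUE)) {
      oto <- c("normal", if (medical) "abnormal" else "normal")
      tymp <- c("normal", "normal")
      aud <- c(if (audiologic) "refer" else "pass", "pass")
      expect_identical(recommend(oto, tymp, aud),
                       oracle(medical, audiologic))
      # the medical flag must fire from tympanometry alone as well
      expect_identical(
        recommend(c("normal", "normal"),
                  c(if (medical) "abnormal" else "normal", "normal"), aud),
        oracle(medical, audiologic)
      )
    }
  }
  outcomes <- c(
    recommend(c("normal", "normal"), c("normal", "normal"), c("pass", "pass")),
    recommend(c("normal", "normal"), c("normal", "normal"), c("refer", "pass")),
    recommend(c("abnormal", "normal"), c("normal", "normal"), c("pass", "pass")),
    recommend(c("abnormal", "normal"), c("normal", "normal"), c("pass", "refer"))
  )
  expect_identical(sort(outcomes),
                   sort(c("pass", "refer_audiologist", "refer_physician",
                          "refer_both")))
  expect_error(recommend(c("normal", NA), c("normal", "normal"),
                         c("pass", "pass")),
               class = "hss_validation_error")
})

test_that("ground truth derives per-ear results and referral from the profiles", {
  # all thresholds at/below the screening level, type A, clear canals
  normal <- make_patient()
  t1 <- derive_ground_truth(normal)
  expect_identical(unlist(t1$audiometry, use.names = FALSE), c("pass", "pass"))
  expect_identical(t1$recommendation, "pass")

  # one ear fails one frequency -> audiologic referral only
  uni <- make_patient(thresholds_right = c(`1000` = 10, `2000` = 45, `4000` = 10))
  t2 <- derive_ground_truth(uni)
  expect_identical(t2$audiometry$right, "refer")
  expect_identical(t2$audiometry$left, "pass")
  expect_identical(t2$recommendation, "refer_audiologist")

  # a threshold exactly at the screening level passes
  edge <- make_patient(thresholds_left = c(`1000` = 20, `2000` = 20, `4000` = 20))
  expect_identical(derive_ground_truth(edge)$audiometry$left, "pass")

  # effusion otoscopy + flat tymp + raised thresholds -> both referrals
  eff <- make_patient(
    oto_left = "effusion", oto_right = "effusion",
    tymp_left = tympanogram_profile(FALSE, ear_canal_volume = 1.0),
    tymp_right = tympanogram_profile(FALSE, ear_canal_volume = 1.0),
    thresholds_left = c(`1000` = 30, `2000` = 30, `4000` = 30),
    thresholds_right = c(`1000` = 30, `2000` = 30, `4000` = 30)
  )
  expect_identical(derive_ground_truth(eff)$recommendation, "refer_both")
})

test_that("ground truth is invariant under demographic randomization", {
  roster <- load_roster()
  pool <- load_names()
  for (base in roster) {
    truth <- derive_ground_truth(base)
    for (seed in c(1, 17, 4242)) {
      pres <- randomize_presentation(base, pool, seed = seed)
      expect_identical(derive_ground_truth(pres), truth)
    }
  }
})

test_that("a compliant scripted session yields audiometry outcomes matching ground truth", {
  roster <- load_roster()
  protocol <- protocol_config()
  for (base in roster) {
    truth <- derive_ground_truth(base)
    s <- run_protocol_session(base, seed = 8)
    ev <- session_events(s)
    tones <- ev[ev$kind == "tone_presented", ]
    for (ear in c("left", "right")) {
      responded_all <- all(tones$responded[tones$ear == ear])
      expect_identical(
        if (responded_all) "pass" else "refer",
        truth$audiometry[[ear]],
        info = paste(base$id, ear)
      )
    }
  }
})

test_that("a fully compliant session produces no findings and correct counters", {
  s <- run_protocol_session(make_patient())
  audit <- check_compliance(s)
  expect_identical(nrow(audit$findings), 0L)
  expect_true(is_compliant(audit))
  expect_identical(nrow(audit$tone_counts), 6L)
  expect_true(all(audit$tone_counts$level == 20))
  expect_identical(audit$positive_responses, 6L)
})

test_that("each single protocol deviation produces exactly one matching finding", {
  base <- make_patient()
  truth <- derive_ground_truth(base)
  notes <- notes_from_truth(truth)
  full <- compliant_actions(notes)

  run_mutated <- function(actions) {
    pres <- randomize_presentation(base, tiny_pool(), seed = 2)
    s <- start_session("T", pres, seed = 2, clock = step_clock())
    run_actions(s, actions)
    check_compliance(s)
  }

  is_tone <- function(a, ear = NULL, f = NULL) {
    a$action == "present_tone" &&
      (is.null(ear) || identical(a$params$ear, ear)) &&
      (is.null(f) || identical(a$params$frequency, f))
  }

  # drop otoscopy entirely -> MISSING_PROCEDURE
  m1 <- Filter(function(a) a$action != "oto_exam", full)
  a1 <- run_mutated(m1)
  expect_identical(a1$findings$code, "MISSING_PROCEDURE")
  expect_match(a1$findings$detail, "otoscopy")

  # drop left-ear tympanometry -> EAR_NOT_TESTED
  m2 <- Filter(function(a) {
    !(a$action == "tymp_exam" && identical(a$params$ear, "left"))
  }, full)
  a2 <- run_mutated(m2)
  expect_identical(a2$findings$code, "EAR_NOT_TESTED")
  expect_match(a2$findings$detail, "tympanometry.*left")

  # drop the right-ear 4000 Hz tone -> MISSING_FREQUENCY(right, 4000)
  m3 <- Filter(function(a) !is_tone(a, "right", 4000), full)
  a3 <- run_mutated(m3)
  expect_identical(a3$findings$code, "MISSING_FREQUENCY")
  expect_match(a3$findings$detail, "right ear never screened at 4000 Hz")

  # present one tone at the wrong level -> one WRONG_LEVEL finding
  m4 <- lapply(full, function(a) {
    if (is_tone(a, "left", 1000)) a$params$level <- 30
    a
  })
  a4 <- run_mutated(m4)
  expect_identical(a4$findings$code, "WRONG_LEVEL")
  expect_match(a4$findings$detail, "30 dB HL")

  # run audiometry before otoscopy -> one OUT_OF_ORDER warning
  tones_first <- c(Filter(function(a) is_tone(a), full),
                   Filter(function(a) !is_tone(a), full))
  a5 <- run_mutated(tones_first)
  expect_identical(a5$findings$code, "OUT_OF_ORDER")
  expect_identical(a5$findings$severity, "warning")

  # save incomplete notes -> INCOMPLETE_NOTES naming the gap
  partial <- notes
  partial$tympanometry_left <- NA_character_
  m6 <- lapply(full, function(a) {
    if (a$action == "save_notes") a$params$notes <- unclass(partial)
    a
  })
  a6 <- run_mutated(m6)
  expect_identical(a6$findings$code, "INCOMPLETE_NOTES")
  expect_match(a6$findings$detail, "tympanometry_left")
})

test_that("wrong-level findings are grouped per off-level presentation set", {
  s <- run_protocol_session(make_patient(), level = 30)
  audit <- check_compliance(s)
  wrong <- audit$findings[audit$findings$code == "WRONG_LEVEL", ]
  expect_identical(nrow(wrong), 6L)  # one per (ear, frequency) set
  expect_identical(unique(audit$findings$code), "WRONG_LEVEL")
})

test_that("compliance requires a closed session", {
  pres <- randomize_presentation(make_patient(), tiny_pool(), seed = 1)
  s <- start_session("T", pres, seed = 1, clock = step_clock())
  expect_error(check_compliance(s), "closed", class = "hss_session_error")
})

test_that("configs load from the bundled JSON files", {
  protocol <- load_protocol()
  expect_equal(protocol$screening_level, 20)
  expect_equal(protocol$required_frequencies, c(1000, 2000, 4000))
  norms <- load_norms()
  expect_equal(norms$peak_pressure, c(-150, 100))
  expect_equal(norms$static_compliance, c(0.3, 1.5))
  expect_equal(norms$ecv$child, c(0.4, 1.0))
  expect_equal(norms$ecv$adult, c(0.6, 2.0))
  expect_error(protocol_config(required_frequencies = numeric()),
               class = "hss_validation_error")
  expect_error(normative_ranges(peak_pressure = c(5, -5)),
               class = "hss_validation_error")
})
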
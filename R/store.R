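# Append-only session store: one JSON record per line (JSONL), behind a small
# storage interface so a different backend could be swapped in.

#' Open (or create) a session store
#'
#' The store is a line-delimited JSON file: every completed, graded session
#' is appended as one immutable record. Records are never modified or
#' deleted, which keeps the training history auditable and the file
#' diffable.
#'
#' @param path Path to the `.jsonl` file; created on first append.
#' @return An object of class `hss_store`.
#' @export
session_store <- function(path) {
  structure(list(path = path), class = "hss_store")
}

#' Build a storable record from a debrief
#'
#' @param report An `hss_debrief` from [debrief()].
#' @param session The corresponding closed `hss_session` (supplies the event
#'   log and notes).
#' @param record_id Unique id; generated from the session end time plus a
#'   random suffix when omitted.
#' @return A list of class `hss_record`.
#' @export
session_record <- function(report, session, record_id = NULL) {
  if (!inherits(report, "hss_debrief")) {
    hss_abort("report must be an hss_debrief", "hss_validation_error")
  }
  record_id <- record_id %||%
    paste0(gsub("[^0-9]", "", substr(report$ended_at, 1, 19)), "-",
           sprintf("%06x", sample.int(16777216L, 1) - 1L))
  events <- lapply(session$events, function(e) {
    list(kind = e$kind, timestamp = iso_time(e$timestamp),
         params = e$params, outcome = e$outcome)
  })
  structure(
    list(
      record_id = record_id,
      timestamp = report$ended_at,
      technician_name = report$technician_name,
      base_id = report$base_id,
      seed = report$seed,
      event_log = events,
      notes = if (is.null(session$notes)) NULL else unclass(session$notes),
      graded_items = report$graded_items,
      n_correct = report$n_correct,
      score = report$score,
      testing_duration_s = report$testing_duration_s,
      total_duration_s = report$total_duration_s,
      findings = report$findings
    ),
    class = "hss_record"
  )
}

record_ids <- function(store) {
  if (!file.exists(store$path)) {
    return(character())
  }
  vapply(read_sessions(store), `[[`, character(1), "record_id")
}

#' Append a session record to the store
#'
#' @param store An [session_store()].
#' @param record An [session_record()].
#' @return The record id, invisibly.
#' @export
append_session <- function(store, record) {
  if (!inherits(record, "hss_record")) {
    hss_abort("record must be an hss_record", "hss_validation_error")
  }
  if (record$record_id %in% record_ids(store)) {
    hss_abort(paste0("duplicate record id '", record$record_id, "'"),
              "hss_store_error")
  }
  line <- as.character(
    jsonlite::toJSON(unclass(record), auto_unbox = TRUE, digits = NA,
                     null = "null")
  )
  ok <- tryCatch({
    con <- file(store$path, open = "a", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(line, con)
    TRUE
  }, error = function(e) {
    hss_abort(paste0("cannot write to store '", store$path, "': ",
                     conditionMessage(e)),
              "hss_store_error")
  }, warning = function(w) {
    hss_abort(paste0("cannot write to store '", store$path, "': ",
                     conditionMessage(w)),
              "hss_store_error")
  })
  invisible(record$record_id)
}

#' Read session records
#'
#' `read_sessions()` returns every record; `fetch_session()` one record by
#' id.
#'
#' @param store An [session_store()].
#' @return A list of `hss_record` objects.
#' @export
read_sessions <- function(store) {
  if (!file.exists(store$path)) {
    hss_abort(paste0("store not found: ", store$path), "hss_store_error")
  }
  lines <- readLines(store$path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
    x$graded_items <- as_tibble(as.data.frame(x$graded_items))
    x$findings <- if (length(x$findings) == 0) {
      tibble(code = character(), detail = character(), severity = character())
    } else {
      as_tibble(as.data.frame(x$findings))
    }
    x$event_log <- jsonlite::fromJSON(
      as.character(jsonlite::toJSON(x$event_log, auto_unbox = TRUE,
                                    digits = NA, null = "null")),
      simplifyVector = FALSE
    )
    structure(x, class = "hss_record")
  })
}

#' @rdname read_sessions
#' @param record_id Record id to fetch.
#' @export
fetch_session <- function(store, record_id) {
  records <- read_sessions(store)
  ids <- vapply(records, `[[`, character(1), "record_id")
  hit <- which(ids == record_id)
  if (length(hit) == 0) {
    hss_abort(paste0("no record with id '", record_id, "'"),
              "hss_store_error")
  }
  records[[hit[1]]]
}

#' A student's session history
#'
#' @param store An [session_store()].
#' @param technician_name The student's name; an unknown name yields an empty
#'   tibble.
#' @return A tibble, chronologically ordered: `timestamp`, `record_id`,
#'   `base_id`, `score`, `testing_duration_s`, `total_duration_s`.
#' @export
student_history <- function(store, technician_name) {
  records <- read_sessions(store)
  rows <- purrr::map_dfr(records, function(r) {
    tibble(
      technician_name = r$technician_name,
      timestamp = r$timestamp,
      record_id = r$record_id,
      base_id = r$base_id,
      score = r$score,
      testing_duration_s = r$testing_duration_s,
      total_duration_s = r$total_duration_s
    )
  })
  if (nrow(rows) == 0) {
    return(tibble(
      timestamp = character(), record_id = character(),
      base_id = character(), score = numeric(),
      testing_duration_s = numeric(), total_duration_s = numeric()
    ))
  }
  rows |>
    dplyr::filter(.data$technician_name == !!technician_name) |>
    dplyr::arrange(.data$timestamp) |>
    dplyr::select(-"technician_name")
}

#' Cross-sectional cohort summary
#'
#' Aggregates every stored session: mean score and durations, per-item error
#' rates (the fraction of sessions in which each of the 7 graded items was
#' answered incorrectly — the cross-sectional view instructors use to spot
#' systematically missed skills), and the number of sessions per base
#' patient.
#'
#' @param store An [session_store()] with at least one record.
#' @return An object of class `hss_cohort` with `n_sessions`, `n_students`,
#'   `mean_score`, `mean_testing_duration_s`, `mean_total_duration_s`,
#'   `item_error_rates` (tibble) and `sessions_per_patient` (tibble).
#' @export
cohort_summary <- function(store) {
  records <- read_sessions(store)
  if (length(records) == 0) {
    hss_abort("empty store: no sessions to summarise", "hss_store_error")
  }
  per_item <- purrr::map_dfr(records, function(r) {
    tibble(
      record_id = r$record_id,
      item = r$graded_items$item,
      correct = r$graded_items$correct
    )
  })
  item_error_rates <- per_item |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      n_incorrect = sum(!.data$correct),
      error_rate = mean(!.data$correct),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$item, GRADE_ITEMS))
  sessions_per_patient <- tibble(
    base_id = vapply(records, `[[`, character(1), "base_id")
  ) |>
    dplyr::count(.data$base_id, name = "n_sessions")
  structure(
    list(
      n_sessions = length(records),
      n_students = length(unique(
        vapply(records, `[[`, character(1), "technician_name")
      )),
      mean_score = mean(vapply(records, `[[`, numeric(1), "score")),
      mean_testing_duration_s = mean(
        vapply(records, `[[`, numeric(1), "testing_duration_s")
      ),
      mean_total_duration_s = mean(
        vapply(records, `[[`, numeric(1), "total_duration_s")
      ),
      item_error_rates = item_error_rates,
      sessions_per_patient = sessions_per_patient
    ),
    class = "hss_cohort"
  )
}

#' @exportS3Method generics::tidy
tidy.hss_cohort <- function(x, ...) {
  x$item_error_rates
}

#' @exportS3Method generics::glance
glance.hss_cohort <- function(x, ...) {
  tibble(
    n_sessions = x$n_sessions,
    n_students = x$n_students,
    mean_score = x$mean_score,
    mean_testing_duration_s = x$mean_testing_duration_s,
    mean_total_duration_s = x$mean_total_duration_s
  )
}

#' @export
print.hss_cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d session(s), %d student(s), mean score %.3f>\n",
              x$n_sessions, x$n_students, x$mean_score))
  print(x$item_error_rates)
  invisible(x)
}

#' Export a cohort summary as CSV
#'
#' Writes a long-format table (`metric`, `group`, `value`) covering the
#' overall aggregates, per-item error rates and sessions per patient.
#'
#' @param cohort An `hss_cohort`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_cohort <- function(cohort, path) {
  long <- dplyr::bind_rows(
    tibble(
      metric = c("n_sessions", "n_students", "mean_score",
                 "mean_testing_duration_s", "mean_total_duration_s"),
      group = NA_character_,
      value = c(cohort$n_sessions, cohort$n_students, cohort$mean_score,
                cohort$mean_testing_duration_s, cohort$mean_total_duration_s)
    ),
    tibble(
      metric = "item_error_rate",
      group = cohort$item_error_rates$item,
      value = cohort$item_error_rates$error_rate
    ),
    tibble(
      metric = "sessions_per_patient",
      group = cohort$sessions_per_patient$base_id,
      value = as.numeric(cohort$sessions_per_patient$n_sessions)
    )
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
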
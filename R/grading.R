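# Automatic grading against ground truth and the debrief report.

#' Grade technician notes against the ground truth
#'
#' Seven equally weighted items are graded: the six per-ear procedure results
#' and the final recommendation. An item is correct exactly when the
#' trainee's answer equals the correct answer; missing answers are incorrect
#' and flagged as missing. The score is the fraction correct (out of 7).
#' Grading is a pure function of notes and truth: no simulated randomness
#' enters it.
#'
#' @param notes An [technician_notes()] object (possibly partial or `NULL`).
#' @param truth An `hss_truth` from [derive_ground_truth()].
#' @return An object of class `hss_grade`: a list with `items` (tibble:
#'   `item`, `student_answer`, `correct_answer`, `correct`, `missing`,
#'   `explanation`), `n_correct` and `score`.
#' @export
#' @examples
#' truth <- derive_ground_truth(load_roster()[["p01"]])
#' notes <- notes_from_truth(truth)
#' grade_session(notes, truth)$score
grade_session <- function(notes, truth) {
  if (!inherits(truth, "hss_truth")) {
    hss_abort("truth must be an hss_truth", "hss_validation_error")
  }
  notes <- as_notes(notes)
  correct_answers <- as_tibble(truth)$correct_answer
  student <- vapply(GRADE_ITEMS, function(s) notes[[s]], character(1))
  missing <- is.na(student)
  correct <- !missing & student == correct_answers
  items <- tibble(
    item = GRADE_ITEMS,
    student_answer = unname(student),
    correct_answer = correct_answers,
    correct = unname(correct),
    missing = unname(missing),
    explanation = truth$explanation
  )
  structure(
    list(
      items = items,
      n_correct = sum(correct),
      score = sum(correct) / length(GRADE_ITEMS)
    ),
    class = "hss_grade"
  )
}

#' Build complete notes that match a ground truth
#'
#' Convenience for demos and self-consistency checks: the notes a perfectly
#' accurate trainee would enter.
#'
#' @param truth An `hss_truth`.
#' @return An `hss_notes` object that grades 7/7 against `truth`.
#' @export
notes_from_truth <- function(truth) {
  technician_notes(
    otoscopy_left = truth$otoscopy$left,
    otoscopy_right = truth$otoscopy$right,
    tympanometry_left = truth$tympanometry$left,
    tympanometry_right = truth$tympanometry$right,
    audiometry_left = truth$audiometry$left,
    audiometry_right = truth$audiometry$right,
    final_recommendation = truth$recommendation
  )
}

#' @export
print.hss_grade <- function(x, ...) {
  cat(sprintf("<grade: %d/7 correct, score %.3f>\n", x$n_correct, x$score))
  print(x$items[, c("item", "student_answer", "correct_answer", "correct")])
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hss_grade <- function(x, ...) {
  x$items
}

#' @exportS3Method generics::glance
glance.hss_grade <- function(x, ...) {
  tibble(n_items = nrow(x$items), n_correct = x$n_correct, score = x$score)
}

#' Assemble the debrief report for a completed session
#'
#' Derives the ground truth for the session's base patient, grades the saved
#' technician notes, audits protocol compliance, and collects the session
#' metadata shown to the facilitator (trainee and subject names, durations,
#' procedures run). This is the report a facilitator and trainee review
#' together after the screening.
#'
#' @param session A closed `hss_session` with notes saved.
#' @param protocol An [protocol_config()] object.
#' @param norms An [normative_ranges()] object.
#' @return An object of class `hss_debrief`.
#' @export
debrief <- function(session, protocol = protocol_config(),
                    norms = normative_ranges()) {
  if (!inherits(session, "hss_session")) {
    hss_abort("session must be an hss_session", "hss_validation_error")
  }
  if (!isTRUE(session$closed)) {
    hss_abort("debrief requires a closed session", "hss_session_error")
  }
  truth <- derive_ground_truth(session$presentation$base,
                               protocol = protocol, norms = norms)
  grade <- grade_session(session$notes, truth)
  compliance <- check_compliance(session, protocol = protocol)
  durations <- session_durations(session)
  events <- session_events(session)
  procedures <- intersect(
    c("oto_exam", "tymp_exam", "tone_presented"), unique(events$kind)
  )
  procedures <- c(oto_exam = "otoscopy", tymp_exam = "tympanometry",
                  tone_presented = "audiometry")[procedures]
  structure(
    list(
      technician_name = session$technician_name,
      subject_name = session$presentation$display_name,
      base_id = session$presentation$base_id,
      seed = session$seed,
      started_at = iso_time(session$started_at),
      ended_at = iso_time(session$ended_at),
      testing_duration_s = durations$testing,
      total_duration_s = durations$total,
      procedures_run = unname(procedures),
      graded_items = grade$items,
      n_correct = grade$n_correct,
      score = grade$score,
      recommendation_correct = truth$recommendation,
      findings = compliance$findings,
      tone_counts = compliance$tone_counts,
      positive_responses = compliance$positive_responses,
      notes_comments = session$notes$comments %||% list(),
      final_comment = session$notes$final_comment %||% ""
    ),
    class = "hss_debrief"
  )
}

#' @exportS3Method generics::tidy
tidy.hss_debrief <- function(x, ...) {
  x$graded_items
}

#' @exportS3Method generics::glance
glance.hss_debrief <- function(x, ...) {
  tibble(
    technician_name = x$technician_name,
    subject_name = x$subject_name,
    base_id = x$base_id,
    score = x$score,
    n_correct = x$n_correct,
    n_findings = nrow(x$findings),
    testing_duration_s = x$testing_duration_s,
    total_duration_s = x$total_duration_s
  )
}

#' @export
print.hss_debrief <- function(x, ...) {
  cat(render_report(x, format = "markdown"))
  invisible(x)
}

#' Render a debrief report
#'
#' `"markdown"` produces the human-readable debrief: a metadata block,
#' the procedures run, a per-item table of trainee vs. correct answers with
#' the case explanation, the recommendation, and the compliance findings
#' (or a fully-compliant line). `"json"` is loss-free: parsing it with
#' [report_from_json()] rebuilds an identical report object.
#'
#' @param report An `hss_debrief`.
#' @param format `"markdown"` or `"json"`.
#' @return A single string.
#' @export
render_report <- function(report, format = c("markdown", "json")) {
  if (!inherits(report, "hss_debrief")) {
    hss_abort("report must be an hss_debrief", "hss_validation_error")
  }
  format <- match.arg(format)
  if (format == "json") {
    payload <- unclass(report)
    payload$graded_items <- as.data.frame(report$graded_items)
    payload$findings <- as.data.frame(report$findings)
    payload$tone_counts <- as.data.frame(report$tone_counts)
    return(as.character(
      jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
    ))
  }
  g <- report$graded_items
  lines <- c(
    "# Hearing screening debrief",
    "",
    paste0("- Technician: ", report$technician_name),
    paste0("- Subject: ", report$subject_name, " (case ", report$base_id, ")"),
    paste0("- Session: ", report$started_at, " to ", report$ended_at),
    sprintf("- Testing duration: %.0f s; total duration: %.0f s",
            report$testing_duration_s, report$total_duration_s),
    paste0("- Seed: ", report$seed),
    "",
    "## Procedures run",
    "",
    if (length(report$procedures_run)) {
      paste0("- ", report$procedures_run)
    } else {
      "- none"
    },
    "",
    "## Graded results",
    "",
    sprintf("Score: %d/7 (%.2f)", report$n_correct, report$score),
    "",
    "| Item | Your answer | Correct answer | Result |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %s | %s |",
            g$item,
            ifelse(g$missing, "(missing)", g$student_answer),
            g$correct_answer,
            ifelse(g$correct, "correct", "incorrect")),
    "",
    paste0("Explanation: ", g$explanation[1]),
    "",
    "## Recommendation",
    "",
    paste0("Correct recommendation: ", report$recommendation_correct),
    "",
    "## Compliance",
    ""
  )
  if (nrow(report$findings) == 0) {
    lines <- c(lines, "Fully compliant with the screening protocol.")
  } else {
    lines <- c(lines, sprintf("- [%s] %s: %s",
                              report$findings$severity,
                              report$findings$code,
                              report$findings$detail))
  }
  lines <- c(lines, "",
             sprintf("Positive responses recorded: %d",
                     report$positive_responses))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname render_report
#' @param json A string produced by `render_report(report, "json")`.
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  x$graded_items <- as_tibble(as.data.frame(x$graded_items))
  x$findings <- if (length(x$findings) == 0) {
    tibble(code = character(), detail = character(), severity = character())
  } else {
    as_tibble(as.data.frame(x$findings))
  }
  x$tone_counts <- if (length(x$tone_counts) == 0) {
    tibble(ear = character(), frequency = numeric(), level = numeric(),
           n = integer(), n_responded = integer())
  } else {
    tc <- as_tibble(as.data.frame(x$tone_counts))
    tc$n <- as.integer(tc$n)
    tc$n_responded <- as.integer(tc$n_responded)
    tc
  }
  x$procedures_run <- as.character(x$procedures_run)
  x$positive_responses <- as.integer(x$positive_responses)
  x$n_correct <- as.integer(x$n_correct)
  x$seed <- as.integer(x$seed)
  if (is.list(x$notes_comments) && length(x$notes_comments) == 0) {
    x$notes_comments <- list()
  }
  structure(x, class = "hss_debrief")
}
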
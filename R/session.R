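# The device/session state machine. A session is an environment-backed S3
# object: operations mutate it in place, append to its timestamped event log,
# and return whatever the clinical action produced (a finding, a tympanogram,
# a hand-raise flag). The log plus the seed is a sufficient statistic — a
# scripted replay reproduces every outcome.

#' Start a screening session
#'
#' Creates the session state machine for one trainee/patient pairing: mode
#' and ear selection, tone controls, an append-only event log, and a private
#' random stream for the subject's responses. Timestamps are read through an
#' injectable clock so durations can be tested with a synthetic clock.
#'
#' @param technician_name The trainee's name (required).
#' @param presentation An [randomize_presentation()] result.
#' @param seed Integer seed for the subject's response stream.
#' @param clock A clock function, e.g. [system_clock()] (default) or
#'   [step_clock()].
#' @return An object of class `hss_session` (environment; mutated in place by
#'   the session operations).
#' @export
#' @examples
#' roster <- load_roster()
#' pres <- randomize_presentation(roster[["p01"]], load_names(), seed = 7)
#' s <- start_session("Student A", pres, seed = 7, clock = step_clock())
#' oto_exam(s, "left")$category
start_session <- function(technician_name, presentation, seed,
                          clock = system_clock()) {
  if (!is.character(technician_name) || length(technician_name) != 1 ||
      !nzchar(technician_name)) {
    hss_abort("technician_name is required", "hss_validation_error")
  }
  if (!inherits(presentation, "hss_presentation")) {
    hss_abort("presentation must be an hss_presentation",
              "hss_validation_error")
  }
  s <- new.env(parent = emptyenv())
  s$technician_name <- technician_name
  s$presentation <- presentation
  s$seed <- as.integer(seed)
  s$rng <- make_rng(seed)
  s$clock <- clock
  s$mode <- NA_character_
  s$selected_ear <- "none"
  s$selected_level <- NA_real_
  s$selected_frequency <- NA_real_
  s$started_at <- clock()
  s$first_test_at <- NULL
  s$ended_at <- NULL
  s$closed <- FALSE
  s$notes <- NULL
  s$events <- list()
  class(s) <- "hss_session"
  s
}

assert_open <- function(session) {
  if (!inherits(session, "hss_session")) {
    hss_abort("not an hss_session", "hss_validation_error")
  }
  if (isTRUE(session$closed)) {
    hss_abort("session is closed", "hss_session_error")
  }
}

log_event <- function(session, kind, params = list(), outcome = list()) {
  session$events[[length(session$events) + 1]] <- list(
    seq = length(session$events) + 1L,
    kind = kind,
    timestamp = session$clock(),
    params = params,
    outcome = outcome
  )
  invisible(session)
}

mark_first_test <- function(session) {
  if (is.null(session$first_test_at)) {
    session$first_test_at <- session$clock()
  }
}

resolve_ear <- function(session, ear) {
  ear <- ear %||% session$selected_ear
  if (is.null(ear) || is.na(ear) || !ear %in% EARS) {
    hss_abort("no ear selected (choose 'left' or 'right')",
              "hss_session_error")
  }
  ear
}

#' Device selection controls
#'
#' Mirror the front-panel controls of the simulated combination audiometer:
#' choose the testing mode, the test ear, and (for audiometry) the
#' presentation level and frequency. Each selection is logged.
#'
#' @param session An open `hss_session`.
#' @param mode One of `otoscopy`, `tympanometry`, `audiometry`.
#' @param ear `left` or `right`.
#' @param level Presentation level in dB HL, from [device_levels()].
#' @param frequency Tone frequency in Hz, from [device_frequencies()].
#' @return The session, invisibly.
#' @export
select_mode <- function(session, mode) {
  assert_open(session)
  if (!mode %in% MODES) {
    hss_abort(paste0("unknown mode '", mode, "'"), "hss_session_error")
  }
  session$mode <- mode
  log_event(session, "select_mode", params = list(mode = mode))
  invisible(session)
}

#' @rdname select_mode
#' @export
select_ear <- function(session, ear) {
  assert_open(session)
  if (!ear %in% EARS) {
    hss_abort(paste0("ear must be 'left' or 'right', got '", ear, "'"),
              "hss_session_error")
  }
  session$selected_ear <- ear
  log_event(session, "select_ear", params = list(ear = ear))
  invisible(session)
}

#' @rdname select_mode
#' @export
set_level <- function(session, level) {
  assert_open(session)
  if (!level %in% device_levels()) {
    hss_abort(
      paste0("level ", level, " dB HL outside the device range (-10..90 in 5 dB steps)"),
      "hss_session_error"
    )
  }
  session$selected_level <- level
  log_event(session, "set_level", params = list(level = level))
  invisible(session)
}

#' @rdname select_mode
#' @export
set_frequency <- function(session, frequency) {
  assert_open(session)
  if (!frequency %in% device_frequencies()) {
    hss_abort(
      paste0("unsupported frequency ", frequency, " Hz (device set: ",
             paste(device_frequencies(), collapse = ", "), ")"),
      "hss_session_error"
    )
  }
  session$selected_frequency <- frequency
  log_event(session, "set_frequency", params = list(frequency = frequency))
  invisible(session)
}

#' Run an otoscopic or tympanometric examination
#'
#' Pressing the "Oto" / "Tymp" button for the selected ear returns the base
#' patient's ground-truth finding for that ear and logs the examination. The
#' first examination or tone of the session starts the testing-portion timer.
#'
#' @param session An open `hss_session`.
#' @param ear `left` or `right`; defaults to the currently selected ear
#'   (an error if none is selected).
#' @return `oto_exam()`: the ear's `hss_otoscopy` finding. `tymp_exam()`: the
#'   ear's `hss_tympanogram` profile.
#' @export
oto_exam <- function(session, ear = NULL) {
  assert_open(session)
  ear <- resolve_ear(session, ear)
  finding <- session$presentation$base$otoscopy[[ear]]
  mark_first_test(session)
  log_event(session, "oto_exam", params = list(ear = ear),
            outcome = list(category = finding$category))
  finding
}

#' @rdname oto_exam
#' @export
tymp_exam <- function(session, ear = NULL) {
  assert_open(session)
  ear <- resolve_ear(session, ear)
  profile <- session$presentation$base$tympanogram[[ear]]
  mark_first_test(session)
  log_event(session, "tymp_exam", params = list(ear = ear),
            outcome = list(peak_present = profile$peak_present))
  profile
}

#' Present a pure tone
#'
#' Presents a tone to the selected ear at the selected frequency and level
#' (all three can also be given explicitly) and returns whether the subject
#' raised their hand. The response is drawn from the psychometric model using
#' the ear's ground-truth threshold at that frequency and the session's
#' private random stream, and the presentation (ear, frequency, level,
#' response) is logged.
#'
#' @inheritParams select_mode
#' @param ear,frequency,level Explicit values; default to the current device
#'   selections.
#' @return `TRUE` if the subject responded.
#' @export
present_tone <- function(session, ear = NULL, frequency = NULL, level = NULL) {
  assert_open(session)
  ear <- resolve_ear(session, ear)
  frequency <- frequency %||% session$selected_frequency
  level <- level %||% session$selected_level
  if (is.na(frequency) || !frequency %in% device_frequencies()) {
    hss_abort(
      paste0("unsupported frequency ", frequency, " Hz (device set: ",
             paste(device_frequencies(), collapse = ", "), ")"),
      "hss_session_error"
    )
  }
  if (is.na(level) || !level %in% device_levels()) {
    hss_abort(paste0("level ", level, " dB HL outside the device range"),
              "hss_session_error")
  }
  aud <- session$presentation$base$audiogram[[ear]]
  threshold <- aud$thresholds[as.character(frequency)]
  if (is.na(threshold)) {
    hss_abort(
      paste0("patient has no threshold defined at ", frequency, " Hz (", ear, " ear)"),
      "hss_session_error"
    )
  }
  params <- aud$inconsistency %||% response_params()
  responded <- simulate_response(level, threshold, params, session$rng)
  mark_first_test(session)
  log_event(session, "tone_presented",
            params = list(ear = ear, frequency = frequency, level = level),
            outcome = list(responded = responded))
  responded
}

#' Save technician notes into the session
#'
#' Notes may be partial; completeness is assessed at grading and compliance
#' time. Saving logs a `notes_saved` event carrying the notes, so a session
#' record is self-contained.
#'
#' @param session An open `hss_session`.
#' @param notes An [technician_notes()] object or a plain list coercible to
#'   one.
#' @return The session, invisibly.
#' @export
save_notes <- function(session, notes) {
  assert_open(session)
  notes <- as_notes(notes)
  session$notes <- notes
  log_event(session, "notes_saved", params = list(notes = unclass(notes)))
  invisible(session)
}

#' Close a session
#'
#' Sets the session end time; no further actions are accepted. The testing
#' duration is the time from the first examination or tone to the close, the
#' total duration from session start to close.
#'
#' @param session An open `hss_session`.
#' @return The session, invisibly.
#' @export
end_session <- function(session) {
  assert_open(session)
  session$ended_at <- session$clock()
  session$closed <- TRUE
  invisible(session)
}

#' Session durations in seconds
#'
#' @param session A closed `hss_session`.
#' @return A list with `testing` (first test to close; 0 if no test was run)
#'   and `total` (start to close), both in seconds.
#' @export
session_durations <- function(session) {
  if (!isTRUE(session$closed)) {
    hss_abort("durations are defined for closed sessions", "hss_session_error")
  }
  total <- as.numeric(difftime(session$ended_at, session$started_at,
                               units = "secs"))
  testing <- if (is.null(session$first_test_at)) {
    0
  } else {
    as.numeric(difftime(session$ended_at, session$first_test_at,
                        units = "secs"))
  }
  list(testing = testing, total = total)
}

#' Tabulate the session event log
#'
#' @param session An `hss_session`.
#' @return A tibble with one row per event: `seq`, `kind`, `timestamp`, and
#'   the common parameters/outcomes (`ear`, `frequency`, `level`, `mode`,
#'   `responded`) flattened into columns.
#' @export
session_events <- function(session) {
  if (length(session$events) == 0) {
    return(tibble(
      seq = integer(), kind = character(),
      timestamp = as.POSIXct(character(), tz = "UTC"),
      ear = character(), frequency = numeric(), level = numeric(),
      mode = character(), responded = logical()
    ))
  }
  purrr::map_dfr(session$events, function(e) {
    tibble(
      seq = e$seq,
      kind = e$kind,
      timestamp = e$timestamp,
      ear = e$params$ear %||% NA_character_,
      frequency = e$params$frequency %||% NA_real_,
      level = e$params$level %||% NA_real_,
      mode = e$params$mode %||% NA_character_,
      responded = e$outcome$responded %||% NA
    )
  })
}

#' @export
print.hss_session <- function(x, ...) {
  cat(sprintf("<session: %s screening %s (%s), %d event(s), %s>\n",
              x$technician_name, x$presentation$display_name,
              x$presentation$base_id, length(x$events),
              if (isTRUE(x$closed)) "closed" else "open"))
  invisible(x)
}

# ---- scripted sessions -------------------------------------------------

#' Load and validate a scripted action file
#'
#' Action files (see `inst/extdata/schemas/actions.schema.json`) drive a
#' session headlessly: a JSON array of `{action, params}` steps using the
#' same operations a trainee would perform at the device.
#'
#' @param path Path to an actions JSON file.
#' @return A validated list of actions.
#' @export
load_actions <- function(path) {
  if (!file.exists(path)) {
    hss_abort(paste0("actions file not found: ", path), "hss_actions_error")
  }
  raw <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) {
      hss_abort(paste0("cannot parse actions '", path, "': ",
                       conditionMessage(e)),
                "hss_actions_error")
    }
  )
  validate_actions(raw)
}

#' @rdname load_actions
#' @param actions A list of `{action, params}` steps.
#' @export
validate_actions <- function(actions) {
  if (!is.list(actions)) {
    hss_abort("actions must be a list of {action, params} steps",
              "hss_actions_error")
  }
  for (i in seq_along(actions)) {
    a <- actions[[i]]
    if (is.null(a$action) || !a$action %in% ACTION_KINDS) {
      hss_abort(
        paste0("step ", i, ": unknown action '", a$action %||% "<missing>",
               "' (known: ", paste(ACTION_KINDS, collapse = ", "), ")"),
        "hss_actions_error"
      )
    }
  }
  actions
}

#' Run a scripted session
#'
#' Applies each action to the session in order. Unknown actions are rejected
#' before anything runs.
#'
#' @param session An open `hss_session`.
#' @param actions A list of actions from [load_actions()] (or built in code).
#' @return The session, invisibly (closed if the script ends with
#'   `end_session`).
#' @export
run_actions <- function(session, actions) {
  actions <- validate_actions(actions)
  for (a in actions) {
    p <- a$params %||% list()
    switch(a$action,
      select_mode = select_mode(session, p$mode),
      select_ear = select_ear(session, p$ear),
      set_level = set_level(session, p$level),
      set_frequency = set_frequency(session, p$frequency),
      oto_exam = oto_exam(session, p$ear),
      tymp_exam = tymp_exam(session, p$ear),
      present_tone = present_tone(session, ear = p$ear,
                                  frequency = p$frequency, level = p$level),
      save_notes = save_notes(session, p$notes),
      end_session = end_session(session)
    )
  }
  invisible(session)
}

#' Replay a session from its event log
#'
#' Re-executes the logged actions against a fresh session with the same
#' presentation and seed (and a synthetic clock). Because the subject's
#' responses are drawn from a seeded private stream, the replay reproduces
#' every outcome — the event log is a sufficient statistic for the session.
#'
#' @param session A closed `hss_session`.
#' @return A fresh, closed `hss_session` with an equivalent event log.
#' @export
replay_session <- function(session) {
  if (!isTRUE(session$closed)) {
    hss_abort("only closed sessions can be replayed", "hss_session_error")
  }
  fresh <- start_session(session$technician_name, session$presentation,
                         seed = session$seed, clock = step_clock())
  for (e in session$events) {
    p <- e$params
    switch(e$kind,
      select_mode = select_mode(fresh, p$mode),
      select_ear = select_ear(fresh, p$ear),
      set_level = set_level(fresh, p$level),
      set_frequency = set_frequency(fresh, p$frequency),
      oto_exam = oto_exam(fresh, p$ear),
      tymp_exam = tymp_exam(fresh, p$ear),
      tone_presented = present_tone(fresh, ear = p$ear,
                                    frequency = p$frequency, level = p$level),
      notes_saved = save_notes(fresh, p$notes)
    )
  }
  end_session(fresh)
  fresh
}
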
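# Shared fixture builders: all fixtures are constructed in code at test time.

# A minimal, fully normal patient with configurable overrides.
make_patient <- function(id = "t01", age_years = 30,
                         thresholds_left = c(`1000` = 10, `2000` = 10, `4000` = 10),
                         thresholds_right = thresholds_left,
                         inconsistency_left = NULL,
                         tymp_left = NULL, tymp_right = NULL,
                         oto_left = "clear_normal", oto_right = "clear_normal") {
  default_tymp <- function() {
    tympanogram_profile(TRUE, peak_pressure = -30, static_compliance = 0.8,
                        ear_canal_volume = if (age_years < 18) 0.7 else 1.2)
  }
  base_patient(
    id = id,
    age_years = age_years,
    condition = "test case",
    case_history_template = "{name} is {age} years old. {Pronoun_subject} is here for a screen.",
    explanation = "Constructed test case.",
    audiogram = list(
      left = audiogram_profile(thresholds_left,
                               inconsistency = inconsistency_left),
      right = audiogram_profile(thresholds_right)
    ),
    tympanogram = list(
      left = tymp_left %||% default_tymp(),
      right = tymp_right %||% default_tymp()
    ),
    otoscopy = list(
      left = otoscopy_finding(oto_left),
      right = otoscopy_finding(oto_right)
    )
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

tiny_pool <- function(n = 4) {
  tibble::tibble(
    name = paste0("Name", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n)
  )
}

# A scripted session that follows the full protocol for any patient:
# otoscopy L/R, tympanometry L/R, tones at `level` at each required frequency
# per ear, complete notes matching `notes`, then close.
compliant_actions <- function(notes, level = 20,
                              frequencies = c(1000, 2000, 4000)) {
  acts <- list(
    list(action = "select_mode", params = list(mode = "otoscopy")),
    list(action = "oto_exam", params = list(ear = "left")),
    list(action = "oto_exam", params = list(ear = "right")),
    list(action = "select_mode", params = list(mode = "tympanometry")),
    list(action = "tymp_exam", params = list(ear = "left")),
    list(action = "tymp_exam", params = list(ear = "right"))
  )
  acts <- c(acts, list(list(action = "select_mode",
                            params = list(mode = "audiometry"))))
  for (ear in c("left", "right")) {
    for (f in frequencies) {
      acts <- c(acts, list(list(
        action = "present_tone",
        params = list(ear = ear, frequency = f, level = level)
      )))
    }
  }
  c(acts,
    list(list(action = "save_notes", params = list(notes = unclass(notes)))),
    list(list(action = "end_session")))
}

# Run a full compliant scripted session for a base patient and return the
# closed session.
run_protocol_session <- function(base, seed = 1,
                                 technician = "Test Student",
                                 notes = NULL, level = 20) {
  pres <- randomize_presentation(base, tiny_pool(), seed = seed)
  truth <- derive_ground_truth(base)
  notes <- notes %||% notes_from_truth(truth)
  s <- start_session(technician, pres, seed = seed, clock = step_clock())
  run_actions(s, compliant_actions(notes, level = level))
  s
}

# Append a graded session record for `base` to a store, with the given notes.
append_record_for <- function(store, base, seed = 1, technician = "S1",
                              notes = NULL, record_id = NULL) {
  s <- run_protocol_session(base, seed = seed, technician = technician,
                            notes = notes)
  rep <- debrief(s)
  rec <- session_record(rep, s, record_id = record_id)
  append_session(store, rec)
  rec
}
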
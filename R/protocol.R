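# Screening protocol: configuration, tympanogram classification, ground-truth
# derivation, referral logic, and event-log compliance auditing.

#' Screening protocol configuration
#'
#' The fixed-level screening protocol: tones are presented at a single level
#' considered normal hearing (20 dB HL by default) at each required frequency
#' (1000, 2000 and 4000 Hz by default) in both ears, with the procedures run
#' in the order otoscopy, tympanometry, audiometry.
#'
#' @param screening_level Presentation level in dB HL.
#' @param required_frequencies Frequencies (Hz) each ear must be screened at;
#'   must be a nonempty subset of [device_frequencies()].
#' @param ears_required Currently always `"both"`.
#' @param enforce_order Audit the otoscopy -> tympanometry -> audiometry
#'   order (deviations are warning-severity findings)?
#' @return An object of class `hss_protocol`.
#' @export
protocol_config <- function(screening_level = 20,
                            required_frequencies = c(1000, 2000, 4000),
                            ears_required = "both",
                            enforce_order = TRUE) {
  screening_level <- as.numeric(screening_level)
  required_frequencies <- as.numeric(required_frequencies)
  if (length(required_frequencies) == 0 ||
      !all(required_frequencies %in% device_frequencies())) {
    hss_abort("required_frequencies must be a nonempty subset of the device set",
              "hss_validation_error")
  }
  if (!screening_level %in% device_levels()) {
    hss_abort("screening_level must be a device-supported level",
              "hss_validation_error")
  }
  structure(
    list(
      screening_level = screening_level,
      required_frequencies = sort(required_frequencies),
      ears_required = ears_required,
      enforce_order = isTRUE(enforce_order)
    ),
    class = "hss_protocol"
  )
}

#' Normative ranges for tympanometry
#'
#' Conventional screening norms: peak pressure -150..+100 daPa, static
#' compliance 0.3..1.5 mL, and equivalent ear canal volume 0.4..1.0 mL for
#' children and 0.6..2.0 mL for adults. All live in configuration so local
#' screening programs can adjust them.
#'
#' @param peak_pressure Length-2 numeric, daPa (min, max).
#' @param static_compliance Length-2 numeric, mL (min, max).
#' @param ecv_child,ecv_adult Length-2 numeric, mL (min, max) per age band.
#' @return An object of class `hss_norms`.
#' @export
normative_ranges <- function(peak_pressure = c(-150, 100),
                             static_compliance = c(0.3, 1.5),
                             ecv_child = c(0.4, 1.0),
                             ecv_adult = c(0.6, 2.0)) {
  ranges <- list(peak_pressure = peak_pressure,
                 static_compliance = static_compliance,
                 ecv_child = ecv_child, ecv_adult = ecv_adult)
  for (nm in names(ranges)) {
    r <- as.numeric(ranges[[nm]])
    if (length(r) != 2 || r[1] >= r[2]) {
      hss_abort(paste0("normative range '", nm, "' must be (min, max) with min < max"),
                "hss_validation_error")
    }
    ranges[[nm]] <- r
  }
  structure(
    list(
      peak_pressure = ranges$peak_pressure,
      static_compliance = ranges$static_compliance,
      ecv = list(child = ranges$ecv_child, adult = ranges$ecv_adult)
    ),
    class = "hss_norms"
  )
}

#' @rdname protocol_config
#' @param path Path to a protocol JSON file.
#' @export
load_protocol <- function(path = hss_file("protocol.json")) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  protocol_config(
    screening_level = x$screening_level %||% 20,
    required_frequencies = x$required_frequencies %||% c(1000, 2000, 4000),
    ears_required = x$ears_required %||% "both",
    enforce_order = x$enforce_order %||% TRUE
  )
}

#' @rdname normative_ranges
#' @param path Path to a norms JSON file.
#' @export
load_norms <- function(path = hss_file("norms.json")) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  normative_ranges(
    peak_pressure = x$peak_pressure %||% c(-150, 100),
    static_compliance = x$static_compliance %||% c(0.3, 1.5),
    ecv_child = x$ecv$child %||% c(0.4, 1.0),
    ecv_adult = x$ecv$adult %||% c(0.6, 2.0)
  )
}

#' Classify a tympanogram
#'
#' Applies the conventional screening typology: type B for a flat (peakless)
#' trace; type C when the compliance peak sits at abnormally negative
#' pressure (below the normative minimum); otherwise A, As or Ad according to
#' whether the static compliance lies within, below or above the normative
#' range. For screening referral, only B, C or an out-of-range ear canal
#' volume count as abnormal — shallow (As) and deep (Ad) peaks are reported
#' but do not trigger referral on their own.
#'
#' @param profile An [tympanogram_profile()].
#' @param age_band `"child"` or `"adult"` (selects the ECV range).
#' @param norms An [normative_ranges()] object.
#' @return A list with `type` (`A`, `As`, `Ad`, `B`, `C`) and `result`
#'   (`normal`/`abnormal`).
#' @export
#' @examples
#' norms <- normative_ranges()
#' classify_tympanogram(
#'   tympanogram_profile(TRUE, peak_pressure = -50,
#'                       static_compliance = 0.8, ear_canal_volume = 1.2),
#'   "adult", norms
#' )
classify_tympanogram <- function(profile, age_band, norms = normative_ranges()) {
  if (!inherits(profile, "hss_tympanogram")) {
    hss_abort("profile must be an hss_tympanogram", "hss_validation_error")
  }
  if (!age_band %in% AGE_BANDS) {
    hss_abort("age_band must be 'child' or 'adult'", "hss_validation_error")
  }
  type <- if (!profile$peak_present) {
    "B"
  } else if (profile$peak_pressure < norms$peak_pressure[1]) {
    "C"
  } else if (profile$static_compliance < norms$static_compliance[1]) {
    "As"
  } else if (profile$static_compliance > norms$static_compliance[2]) {
    "Ad"
  } else {
    "A"
  }
  ecv_range <- norms$ecv[[age_band]]
  ecv_ok <- profile$ear_canal_volume >= ecv_range[1] &&
    profile$ear_canal_volume <= ecv_range[2]
  result <- if (type %in% c("B", "C") || !ecv_ok) "abnormal" else "normal"
  list(type = type, result = result)
}

#' Referral recommendation from per-ear screening results
#'
#' A medical flag is raised when any otoscopy or tympanometry result is
#' abnormal; an audiologic flag when any ear does not pass the pure-tone
#' screen. The four flag combinations map to `pass`, `refer_audiologist`,
#' `refer_physician` and `refer_both`.
#'
#' @param oto_results,tymp_results Character vectors (one entry per ear) of
#'   `normal`/`abnormal`.
#' @param aud_results Character vector (one entry per ear) of `pass`/`refer`.
#' @return A single recommendation string.
#' @export
#' @examples
#' recommend(c("normal", "normal"), c("normal", "normal"), c("pass", "pass"))
#' recommend(c("normal", "abnormal"), c("normal", "normal"), c("pass", "refer"))
recommend <- function(oto_results, tymp_results, aud_results) {
  results <- c(oto_results, tymp_results, aud_results)
  if (length(oto_results) != 2 || length(tymp_results) != 2 ||
      length(aud_results) != 2 || anyNA(results)) {
    hss_abort("all six per-ear results are required", "hss_validation_error")
  }
  if (!all(c(oto_results, tymp_results) %in% c("normal", "abnormal")) ||
      !all(aud_results %in% c("pass", "refer"))) {
    hss_abort("invalid result value", "hss_validation_error")
  }
  medical <- any(c(oto_results, tymp_results) == "abnormal")
  audiologic <- any(aud_results == "refer")
  if (medical && audiologic) {
    "refer_both"
  } else if (medical) {
    "refer_physician"
  } else if (audiologic) {
    "refer_audiologist"
  } else {
    "pass"
  }
}

#' Derive the ground truth for a base patient
#'
#' The correct per-ear results and recommendation are computed
#' deterministically from the patient's clinical profiles: otoscopy from the
#' finding's normality flag; tympanometry via [classify_tympanogram()];
#' audiometry per ear is `refer` exactly when any threshold at a required
#' frequency exceeds the screening level (a threshold equal to the screening
#' level is audible, hence a pass); the recommendation via [recommend()].
#' Demographic randomization never changes the ground truth.
#'
#' @param base An `hss_patient` (or an `hss_presentation`, whose base is
#'   used).
#' @param protocol An [protocol_config()] object.
#' @param norms An [normative_ranges()] object.
#' @return An object of class `hss_truth`: per-ear results, tympanogram
#'   types, recommendation and the case explanation.
#' @export
#' @examples
#' truth <- derive_ground_truth(load_roster()[["p01"]])
#' truth$recommendation
derive_ground_truth <- function(base, protocol = protocol_config(),
                                norms = normative_ranges()) {
  if (inherits(base, "hss_presentation")) {
    base <- base$base
  }
  if (!inherits(base, "hss_patient")) {
    hss_abort("base must be an hss_patient", "hss_validation_error")
  }
  oto <- vapply(EARS, function(e) {
    if (base$otoscopy[[e]]$is_normal) "normal" else "abnormal"
  }, character(1))
  tymp_class <- lapply(EARS, function(e) {
    classify_tympanogram(base$tympanogram[[e]], base$age_band, norms)
  })
  names(tymp_class) <- EARS
  tymp <- vapply(tymp_class, `[[`, character(1), "result")
  aud <- vapply(EARS, function(e) {
    thr <- base$audiogram[[e]]$thresholds
    req <- thr[as.character(protocol$required_frequencies)]
    if (any(req > protocol$screening_level)) "refer" else "pass"
  }, character(1))
  structure(
    list(
      base_id = base$id,
      otoscopy = as.list(oto),
      tympanometry = as.list(tymp),
      tympanogram_types = lapply(tymp_class, `[[`, "type"),
      audiometry = as.list(aud),
      recommendation = recommend(oto, tymp, aud),
      explanation = base$explanation
    ),
    class = "hss_truth"
  )
}

#' @export
print.hss_truth <- function(x, ...) {
  cat(sprintf("<ground truth for %s: oto %s/%s, tymp %s/%s (%s/%s), aud %s/%s -> %s>\n",
              x$base_id, x$otoscopy$left, x$otoscopy$right,
              x$tympanometry$left, x$tympanometry$right,
              x$tympanogram_types$left, x$tympanogram_types$right,
              x$audiometry$left, x$audiometry$right, x$recommendation))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.hss_truth <- function(x, ...) {
  tibble(
    item = c(NOTE_SLOTS, "final_recommendation"),
    correct_answer = c(
      x$otoscopy$left, x$otoscopy$right,
      x$tympanometry$left, x$tympanometry$right,
      x$audiometry$left, x$audiometry$right,
      x$recommendation
    )
  )
}

#' Audit a session's event log against the protocol
#'
#' Checks that the proper procedure was followed and the proper tests were
#' run: all three procedures performed, both ears examined per procedure,
#' every required frequency presented in every tested ear, all tones at the
#' screening level, procedures in protocol order, and notes complete. Each
#' deviation is reported as a finding with a code
#' (`MISSING_PROCEDURE`, `EAR_NOT_TESTED`, `MISSING_FREQUENCY`, `WRONG_LEVEL`,
#' `OUT_OF_ORDER`, `INCOMPLETE_NOTES`) and a human-readable detail; an empty
#' finding table means the session was fully compliant. Order deviations are
#' warning severity, everything else is a violation. The audit also tallies
#' tone presentations per ear/frequency/level and the number of positive
#' (hand-raise) responses — the counters screening guidelines ask
#' facilitators to review.
#'
#' @param session A closed `hss_session` (see [start_session()]).
#' @param protocol An [protocol_config()] object.
#' @param notes Technician notes; defaults to the notes saved in the session.
#' @return An object of class `hss_compliance` with `findings` (tibble:
#'   `code`, `detail`, `severity`), `tone_counts` (tibble: `ear`,
#'   `frequency`, `level`, `n`, `n_responded`) and `positive_responses`.
#' @export
check_compliance <- function(session, protocol = protocol_config(),
                             notes = NULL) {
  if (!inherits(session, "hss_session")) {
    hss_abort("session must be an hss_session", "hss_validation_error")
  }
  if (!isTRUE(session$closed)) {
    hss_abort("compliance is audited on closed sessions only",
              "hss_session_error")
  }
  events <- session_events(session)
  notes <- as_notes(notes %||% session$notes)

  findings <- list()
  add <- function(code, detail, severity = "violation") {
    findings[[length(findings) + 1]] <<- tibble(
      code = code, detail = detail, severity = severity
    )
  }

  proc_kind <- c(otoscopy = "oto_exam", tympanometry = "tymp_exam",
                 audiometry = "tone_presented")
  proc_events <- lapply(proc_kind, function(k) events[events$kind == k, ])

  for (proc in names(proc_kind)) {
    ev <- proc_events[[proc]]
    if (nrow(ev) == 0) {
      add("MISSING_PROCEDURE", paste0(proc, " was never performed"))
    } else {
      for (ear in EARS) {
        if (!ear %in% ev$ear) {
          add("EAR_NOT_TESTED", paste0(proc, ": ", ear, " ear not tested"))
        }
      }
    }
  }

  tones <- proc_events$audiometry
  if (nrow(tones) > 0) {
    for (ear in intersect(EARS, unique(tones$ear))) {
      ear_tones <- tones[tones$ear == ear, ]
      for (f in setdiff(protocol$required_frequencies, ear_tones$frequency)) {
        add("MISSING_FREQUENCY",
            paste0("audiometry: ", ear, " ear never screened at ", f, " Hz"))
      }
    }
    off <- dplyr::distinct(
      tones[tones$level != protocol$screening_level,
            c("ear", "frequency", "level")]
    )
    for (i in seq_len(nrow(off))) {
      add("WRONG_LEVEL",
          sprintf("audiometry: %s ear at %g Hz presented at %g dB HL (protocol: %g)",
                  off$ear[i], off$frequency[i], off$level[i],
                  protocol$screening_level))
    }
  }

  if (protocol$enforce_order) {
    firsts <- vapply(proc_events, function(ev) {
      if (nrow(ev) == 0) NA_real_ else min(ev$seq)
    }, numeric(1))
    performed <- firsts[!is.na(firsts)]
    if (length(performed) > 1 && is.unsorted(performed)) {
      add("OUT_OF_ORDER",
          paste0("procedures run in the order ",
                 paste(names(sort(performed)), collapse = " -> "),
                 " (protocol: otoscopy -> tympanometry -> audiometry)"),
          severity = "warning")
    }
  }

  comp <- notes_completeness(notes)
  if (!comp$complete) {
    add("INCOMPLETE_NOTES",
        paste0("notes missing: ", paste(comp$missing, collapse = ", ")))
  }

  findings <- if (length(findings) == 0) {
    tibble(code = character(), detail = character(), severity = character())
  } else {
    dplyr::bind_rows(findings)
  }

  tone_counts <- if (nrow(tones) == 0) {
    tibble(ear = character(), frequency = numeric(), level = numeric(),
           n = integer(), n_responded = integer())
  } else {
    tones |>
      dplyr::group_by(.data$ear, .data$frequency, .data$level) |>
      dplyr::summarise(
        n = dplyr::n(),
        n_responded = sum(.data$responded),
        .groups = "drop"
      )
  }

  structure(
    list(
      findings = findings,
      tone_counts = tone_counts,
      positive_responses = if (nrow(tones)) sum(tones$responded) else 0L
    ),
    class = "hss_compliance"
  )
}

#' @rdname check_compliance
#' @param compliance An `hss_compliance` object.
#' @export
is_compliant <- function(compliance) {
  nrow(compliance$findings) == 0
}

#' @export
print.hss_compliance <- function(x, ...) {
  if (is_compliant(x)) {
    cat("<compliance: fully compliant>\n")
  } else {
    cat("<compliance: ", nrow(x$findings), " finding(s)>\n", sep = "")
    for (i in seq_len(nrow(x$findings))) {
      cat(sprintf("  [%s] %s: %s\n", x$findings$severity[i],
                  x$findings$code[i], x$findings$detail[i]))
    }
  }
  invisible(x)
}
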
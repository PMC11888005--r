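# Virtual-patient data model: audiogram / tympanogram / otoscopy ground truth
# per ear, roster loading and validation, and demographic randomization.

#' Audiometric frequencies and levels supported by the simulated device
#'
#' The simulated combination audiometer supports a superset of the screening
#' protocol: six octave/inter-octave frequencies and presentation levels from
#' -10 to 90 dB HL in 5 dB steps.
#'
#' @return Numeric vector of frequencies (Hz) or levels (dB HL).
#' @export
device_frequencies <- function() {
  c(250, 500, 1000, 2000, 4000, 8000)
}

#' @rdname device_frequencies
#' @export
device_levels <- function() {
  seq(-10, 90, by = 5)
}

#' Construct per-ear clinical profiles
#'
#' Building blocks of a [base_patient()]: the pure-tone audiogram (thresholds
#' in dB HL by frequency, with optional response-inconsistency parameters),
#' the tympanogram (peak pressure in daPa, static compliance and ear canal
#' volume in mL) and the categorical otoscopic finding.
#'
#' @param thresholds Named numeric vector, names are frequencies in Hz drawn
#'   from [device_frequencies()], values are thresholds in dB HL (-10..120).
#' @param inconsistency Optional [response_params()] (or list coercible to
#'   one); `NULL` means a deterministic step listener.
#' @return `hss_audiogram`, `hss_tympanogram` or `hss_otoscopy` objects.
#' @export
#' @examples
#' audiogram_profile(c(`1000` = 10, `2000` = 15, `4000` = 10))
audiogram_profile <- function(thresholds, inconsistency = NULL) {
  if (is.list(thresholds)) {
    thresholds <- unlist(thresholds)
  }
  if (!is.numeric(thresholds) || is.null(names(thresholds)) ||
      !all(nzchar(names(thresholds)))) {
    hss_abort("thresholds must be a named numeric vector (names = Hz)",
              "hss_roster_error")
  }
  freqs <- suppressWarnings(as.numeric(names(thresholds)))
  if (anyNA(freqs) || !all(freqs %in% device_frequencies())) {
    hss_abort("threshold frequencies must belong to the device set",
              "hss_roster_error")
  }
  if (any(thresholds < -10 | thresholds > 120)) {
    hss_abort("thresholds must lie in -10..120 dB HL", "hss_roster_error")
  }
  if (!is.null(inconsistency)) {
    inconsistency <- as_response_params(inconsistency)
  }
  structure(
    list(thresholds = thresholds[order(freqs)], inconsistency = inconsistency),
    class = "hss_audiogram"
  )
}

#' @rdname audiogram_profile
#' @param peak_present Whether the tympanogram shows a compliance peak
#'   (`FALSE` = flat, type B trace).
#' @param peak_pressure Middle-ear pressure at the peak, daPa (only when a
#'   peak is present; -400..200).
#' @param static_compliance Peak compensated static compliance, mL (>= 0).
#' @param ear_canal_volume Equivalent ear canal volume, mL (> 0).
#' @export
tympanogram_profile <- function(peak_present, peak_pressure = NULL,
                                static_compliance = NULL, ear_canal_volume) {
  if (!is.logical(peak_present) || length(peak_present) != 1 ||
      is.na(peak_present)) {
    hss_abort("peak_present must be TRUE or FALSE", "hss_roster_error")
  }
  if (!is.numeric(ear_canal_volume) || ear_canal_volume <= 0) {
    hss_abort("ear_canal_volume must be > 0 mL", "hss_roster_error")
  }
  if (peak_present) {
    if (is.null(peak_pressure) || is.null(static_compliance)) {
      hss_abort("a peaked tympanogram needs peak_pressure and static_compliance",
                "hss_roster_error")
    }
    if (peak_pressure < -400 || peak_pressure > 200) {
      hss_abort("peak_pressure must lie in -400..200 daPa", "hss_roster_error")
    }
    if (static_compliance < 0) {
      hss_abort("static_compliance must be >= 0 mL", "hss_roster_error")
    }
  } else {
    peak_pressure <- NULL
    static_compliance <- NULL
  }
  structure(
    list(
      peak_present = peak_present,
      peak_pressure = peak_pressure,
      static_compliance = static_compliance,
      ear_canal_volume = ear_canal_volume
    ),
    class = "hss_tympanogram"
  )
}

#' @rdname audiogram_profile
#' @param category Otoscopic finding category, one of `clear_normal`,
#'   `occluding_cerumen`, `erythema`, `effusion`, `perforation`, `pe_tube`,
#'   `foreign_body`, `other`.
#' @param description Free-text description shown to the trainee.
#' @param image_ref Optional opaque path to an otoscopic image asset.
#' @export
otoscopy_finding <- function(category, description = "", image_ref = NULL) {
  if (!is.character(category) || length(category) != 1 ||
      !category %in% OTO_CATEGORIES) {
    hss_abort(
      paste0("otoscopy category must be one of: ",
             paste(OTO_CATEGORIES, collapse = ", ")),
      "hss_roster_error"
    )
  }
  structure(
    list(
      category = category,
      is_normal = identical(category, "clear_normal"),
      description = description,
      image_ref = image_ref
    ),
    class = "hss_otoscopy"
  )
}

#' Construct a base (ground-truth) virtual patient
#'
#' A base patient is a clinical case with known per-ear ground truth in all
#' three screening modalities, plus a case-history template with demographic
#' placeholders (`{name}`, `{age}`, `{pronoun_subject}`, ...) that is rendered
#' when the patient is demographically randomized.
#'
#' @param id Unique roster token, e.g. `"p01"`.
#' @param age_years Base age in years; the band (`child` < 18, else `adult`)
#'   is derived and preserved under randomization.
#' @param condition Short condition label (revealed only on request).
#' @param case_history_template Backstory text with placeholders.
#' @param explanation Text justifying the correct results; quoted in debrief
#'   reports.
#' @param audiogram,tympanogram,otoscopy Named lists with `left` and `right`
#'   profiles ([audiogram_profile()] etc.).
#' @return An object of class `hss_patient`.
#' @export
base_patient <- function(id, age_years, condition, case_history_template,
                         explanation, audiogram, tympanogram, otoscopy) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id)) {
    hss_abort("patient id must be a nonempty string", "hss_roster_error")
  }
  if (!is.numeric(age_years) || age_years <= 0) {
    hss_abort(paste0("patient '", id, "': age_years must be positive"),
              "hss_roster_error")
  }
  for (modality in list(audiogram = audiogram, tympanogram = tympanogram,
                        otoscopy = otoscopy)) {
    if (!all(EARS %in% names(modality))) {
      hss_abort(paste0("patient '", id, "': every modality needs left and right profiles"),
                "hss_roster_error")
    }
  }
  p <- structure(
    list(
      id = id,
      age_years = age_years,
      age_band = if (age_years < 18) "child" else "adult",
      condition = condition,
      case_history_template = case_history_template,
      explanation = explanation,
      audiogram = audiogram[EARS],
      tympanogram = tympanogram[EARS],
      otoscopy = otoscopy[EARS]
    ),
    class = "hss_patient"
  )
  validate_patient(p)
  p
}

# Field-path errors reference the patient id so roster problems are traceable.
validate_patient <- function(p, required_frequencies = c(1000, 2000, 4000)) {
  for (ear in EARS) {
    aud <- p$audiogram[[ear]]
    if (!inherits(aud, "hss_audiogram")) {
      hss_abort(paste0("patient '", p$id, "': audiogram.", ear, " is missing or invalid"),
                "hss_roster_error")
    }
    have <- as.numeric(names(aud$thresholds))
    missing <- setdiff(required_frequencies, have)
    if (length(missing) > 0) {
      hss_abort(
        paste0("patient '", p$id, "': audiogram.", ear,
               ".thresholds lacks required frequencies: ",
               paste(missing, collapse = ", "), " Hz"),
        "hss_roster_error"
      )
    }
    if (!inherits(p$tympanogram[[ear]], "hss_tympanogram")) {
      hss_abort(paste0("patient '", p$id, "': tympanogram.", ear, " is missing or invalid"),
                "hss_roster_error")
    }
    if (!inherits(p$otoscopy[[ear]], "hss_otoscopy")) {
      hss_abort(paste0("patient '", p$id, "': otoscopy.", ear, " is missing or invalid"),
                "hss_roster_error")
    }
  }
  invisible(p)
}

#' @export
print.hss_patient <- function(x, ...) {
  cat(sprintf("<patient %s: %s %s, %d y, %s>\n",
              x$id, x$age_band, x$condition, round(x$age_years),
              paste0("oto ", x$otoscopy$left$category, "/",
                     x$otoscopy$right$category)))
  invisible(x)
}

patient_from_list <- function(x) {
  need <- c("id", "age_years", "case_history_template", "explanation",
            "audiogram", "tympanogram", "otoscopy")
  id <- x$id %||% "<missing id>"
  for (f in need) {
    if (is.null(x[[f]])) {
      hss_abort(paste0("patient '", id, "': missing required field '", f, "'"),
                "hss_roster_error")
    }
  }
  parse_ear <- function(block, field, fn) {
    out <- list()
    for (ear in EARS) {
      if (is.null(block[[ear]])) {
        hss_abort(paste0("patient '", id, "': missing field '", field, ".", ear, "'"),
                  "hss_roster_error")
      }
      out[[ear]] <- withCallingHandlers(
        fn(block[[ear]]),
        hss_error = function(e) {
          hss_abort(paste0("patient '", id, "', field '", field, ".", ear, "': ",
                           conditionMessage(e)),
                    "hss_roster_error")
        }
      )
    }
    out
  }
  base_patient(
    id = x$id,
    age_years = x$age_years,
    condition = x$condition %||% "unspecified",
    case_history_template = x$case_history_template,
    explanation = x$explanation,
    audiogram = parse_ear(x$audiogram, "audiogram", function(a) {
      audiogram_profile(a$thresholds, inconsistency = a$inconsistency)
    }),
    tympanogram = parse_ear(x$tympanogram, "tympanogram", function(t) {
      tympanogram_profile(
        peak_present = isTRUE(t$peak_present),
        peak_pressure = t$peak_pressure,
        static_compliance = t$static_compliance,
        ear_canal_volume = t$ear_canal_volume
      )
    }),
    otoscopy = parse_ear(x$otoscopy, "otoscopy", function(o) {
      otoscopy_finding(
        category = o$category %||% "<missing>",
        description = o$description %||% "",
        image_ref = o$image_ref
      )
    })
  )
}

patient_to_list <- function(p) {
  ear_block <- function(get) setNames(lapply(EARS, get), EARS)
  list(
    id = p$id,
    age_years = p$age_years,
    condition = p$condition,
    case_history_template = p$case_history_template,
    explanation = p$explanation,
    audiogram = ear_block(function(e) {
      a <- p$audiogram[[e]]
      out <- list(thresholds = as.list(a$thresholds))
      if (!is.null(a$inconsistency)) {
        out$inconsistency <- unclass(a$inconsistency)
      }
      out
    }),
    tympanogram = ear_block(function(e) {
      t <- p$tympanogram[[e]]
      Filter(Negate(is.null), list(
        peak_present = t$peak_present,
        peak_pressure = t$peak_pressure,
        static_compliance = t$static_compliance,
        ear_canal_volume = t$ear_canal_volume
      ))
    }),
    otoscopy = ear_block(function(e) {
      o <- p$otoscopy[[e]]
      Filter(Negate(is.null), list(
        category = o$category,
        description = o$description,
        image_ref = o$image_ref
      ))
    })
  )
}

#' Load and write patient rosters
#'
#' Rosters are UTF-8 JSON files holding a list of base patients (see
#' `inst/extdata/schemas/roster.schema.json` for the format). Loading
#' validates every patient and fails with the offending patient id and field
#' path; ids must be unique. `write_roster()` and `load_roster()` round-trip.
#'
#' @param path Path to a roster JSON file; `load_roster()` defaults to the
#'   bundled 10-patient roster.
#' @return `load_roster()`: a named list of `hss_patient` objects (class
#'   `hss_roster`). `write_roster()`: the path, invisibly.
#' @export
#' @examples
#' roster <- load_roster()
#' length(roster)
load_roster <- function(path = hss_file("roster.json")) {
  if (!file.exists(path)) {
    hss_abort(paste0("roster file not found: ", path), "hss_roster_error")
  }
  raw <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) {
      hss_abort(paste0("cannot parse roster '", path, "': ",
                       conditionMessage(e)),
                "hss_roster_error")
    }
  )
  entries <- raw$patients %||% raw
  if (!is.list(entries) || length(entries) == 0) {
    hss_abort("roster contains no patients", "hss_roster_error")
  }
  patients <- lapply(entries, patient_from_list)
  ids <- vapply(patients, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    hss_abort(paste0("duplicate patient id(s): ", paste(dup, collapse = ", ")),
              "hss_roster_error")
  }
  structure(setNames(patients, ids), class = "hss_roster")
}

#' @rdname load_roster
#' @param roster A roster (list of `hss_patient`).
#' @export
write_roster <- function(roster, path) {
  entries <- lapply(unname(roster), patient_to_list)
  jsonlite::write_json(list(patients = entries), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a name pool
#'
#' The name pool pairs each name with a sex tag so that the randomly drawn
#' name and the assigned sex never conflict. The bundled pool has 100 diverse
#' entries.
#'
#' @param path Path to a names JSON file (array of `{name, sex}` objects).
#' @return A tibble with columns `name` and `sex`.
#' @export
load_names <- function(path = hss_file("names.json")) {
  raw <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) {
      hss_abort(paste0("cannot parse name pool '", path, "': ",
                       conditionMessage(e)),
                "hss_validation_error")
    }
  )
  pool <- tibble(
    name = vapply(raw, function(x) x$name %||% NA_character_, character(1)),
    sex = vapply(raw, function(x) x$sex %||% NA_character_, character(1))
  )
  if (nrow(pool) == 0 || anyNA(pool$name) || anyNA(pool$sex) ||
      !all(pool$sex %in% c("female", "male"))) {
    hss_abort("name pool entries must each have a name and a female/male sex tag",
              "hss_validation_error")
  }
  pool
}

#' Demographically randomize a base patient
#'
#' Produces the presentation the trainee sees: a name (with matching sex tag)
#' drawn from the pool, the age jittered by a uniform integer offset of up to
#' 10% of the base age (at least 1 year) but clamped so the child/adult band
#' is preserved, and the backstory rendered with the new demographics. All
#' clinical ground truth is carried over from the base patient unchanged, so
#' the same case can be replayed under many guises. Deterministic in
#' `(base, name_pool, seed)`.
#'
#' @param base An `hss_patient`.
#' @param name_pool A tibble from [load_names()].
#' @param seed Integer seed; recorded in the presentation.
#' @return An object of class `hss_presentation`.
#' @export
#' @examples
#' roster <- load_roster()
#' pres <- randomize_presentation(roster[["p01"]], load_names(), seed = 42)
#' pres$display_name
randomize_presentation <- function(base, name_pool, seed) {
  if (!inherits(base, "hss_patient")) {
    hss_abort("base must be an hss_patient", "hss_validation_error")
  }
  if (!is.data.frame(name_pool) || nrow(name_pool) == 0) {
    hss_abort("name pool is empty", "hss_validation_error")
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    hss_abort("a single integer seed is required", "hss_validation_error")
  }
  seed <- as.integer(seed)
  draw <- withr::with_seed(seed, {
    i <- sample.int(nrow(name_pool), 1)
    jmax <- max(1L, as.integer(round(0.1 * base$age_years)))
    offset <- sample(seq(-jmax, jmax), 1)
    list(i = i, offset = offset)
  })
  age <- as.integer(round(base$age_years)) + draw$offset
  age <- if (base$age_band == "child") {
    min(max(age, 3L), 17L)
  } else {
    min(max(age, 18L), 95L)
  }
  sex <- name_pool$sex[draw$i]
  pr <- pronoun_set(sex)
  values <- list(
    name = name_pool$name[draw$i],
    age = age,
    sex = sex,
    pronoun_subject = pr$subject,
    pronoun_object = pr$object,
    pronoun_possessive = pr$possessive,
    Pronoun_subject = capitalize(pr$subject),
    Pronoun_object = capitalize(pr$object),
    Pronoun_possessive = capitalize(pr$possessive)
  )
  structure(
    list(
      base = base,
      base_id = base$id,
      display_name = name_pool$name[draw$i],
      sex = sex,
      age_years = age,
      backstory = render_template(base$case_history_template, values),
      seed = seed
    ),
    class = "hss_presentation"
  )
}

#' @export
print.hss_presentation <- function(x, ...) {
  cat(sprintf("<presentation of %s: %s, %s, %d y (seed %d)>\n",
              x$base_id, x$display_name, x$sex, x$age_years, x$seed))
  invisible(x)
}

#' Count distinct patient profiles
#'
#' The number of distinct (base patient, name) pairs the randomizer can
#' produce; sex is determined by the name tag and age jitter is excluded, so
#' this is a conservative lower bound on the presented variety. The bundled
#' roster and pool yield 10 x 100 = 1000.
#'
#' @param roster A roster from [load_roster()].
#' @param name_pool A name pool from [load_names()].
#' @return An integer count.
#' @export
count_profile_space <- function(roster, name_pool) {
  length(roster) * nrow(name_pool)
}

#' Tabulate a roster
#'
#' One row per base patient. Ground-truth columns (condition and correct
#' recommendation) are only included when `reveal = TRUE`, so the table can be
#' shown to trainees without spoiling the cases.
#'
#' @param roster A roster from [load_roster()].
#' @param reveal Include ground-truth columns?
#' @param protocol,norms Configs used to derive the revealed recommendation.
#' @return A tibble.
#' @export
roster_table <- function(roster, reveal = FALSE,
                         protocol = protocol_config(),
                         norms = normative_ranges()) {
  out <- tibble(
    id = vapply(roster, `[[`, character(1), "id"),
    age_band = vapply(roster, `[[`, character(1), "age_band"),
    age_years = vapply(roster, `[[`, numeric(1), "age_years")
  )
  if (reveal) {
    truths <- lapply(roster, derive_ground_truth,
                     protocol = protocol, norms = norms)
    out$condition <- vapply(roster, `[[`, character(1), "condition")
    out$recommendation <- vapply(truths, `[[`, character(1), "recommendation")
  }
  out
}
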
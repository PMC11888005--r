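# Technician notes: the trainee's per-procedure, per-ear results and final
# recommendation, validated against the result enums.

slot_values <- function(slot) {
  if (startsWith(slot, "audiometry")) c("pass", "refer") else c("normal", "abnormal")
}

#' Technician notes for a screening session
#'
#' Captures what the trainee records: a result for each procedure and ear
#' (otoscopy and tympanometry: `normal`/`abnormal`; audiometry:
#' `pass`/`refer`), optional free-text comments per procedure, and the final
#' recommendation (`pass`, `refer_audiologist`, `refer_physician`,
#' `refer_both`) with a closing comment. Partial notes are allowed — missing
#' slots are `NA` and surface later as incomplete-notes compliance findings
#' and missing-marked graded items.
#'
#' @param otoscopy_left,otoscopy_right,tympanometry_left,tympanometry_right
#'   `"normal"` or `"abnormal"` (or `NA`).
#' @param audiometry_left,audiometry_right `"pass"` or `"refer"` (or `NA`).
#' @param final_recommendation One of the four recommendation values (or `NA`).
#' @param comments Named list of free-text comments (`otoscopy`,
#'   `tympanometry`, `audiometry`); never auto-scored.
#' @param final_comment Closing free-text comment.
#' @return An object of class `hss_notes`.
#' @export
#' @examples
#' technician_notes(
#'   otoscopy_left = "normal", otoscopy_right = "normal",
#'   tympanometry_left = "normal", tympanometry_right = "normal",
#'   audiometry_left = "pass", audiometry_right = "pass",
#'   final_recommendation = "pass"
#' )
technician_notes <- function(otoscopy_left = NA, otoscopy_right = NA,
                             tympanometry_left = NA, tympanometry_right = NA,
                             audiometry_left = NA, audiometry_right = NA,
                             final_recommendation = NA,
                             comments = list(), final_comment = "") {
  results <- list(
    otoscopy_left = otoscopy_left, otoscopy_right = otoscopy_right,
    tympanometry_left = tympanometry_left,
    tympanometry_right = tympanometry_right,
    audiometry_left = audiometry_left, audiometry_right = audiometry_right
  )
  for (slot in NOTE_SLOTS) {
    v <- results[[slot]]
    if (length(v) != 1) {
      hss_abort(paste0("note slot '", slot, "' must be a single value"),
                "hss_notes_error")
    }
    if (!is.na(v) && !v %in% slot_values(slot)) {
      hss_abort(
        paste0("note slot '", slot, "' must be one of ",
               paste(slot_values(slot), collapse = "/"),
               ", got '", v, "'"),
        "hss_notes_error"
      )
    }
    results[[slot]] <- if (is.na(v)) NA_character_ else as.character(v)
  }
  if (length(final_recommendation) != 1 ||
      (!is.na(final_recommendation) &&
       !final_recommendation %in% RECOMMENDATIONS)) {
    hss_abort(
      paste0("final_recommendation must be one of ",
             paste(RECOMMENDATIONS, collapse = "/")),
      "hss_notes_error"
    )
  }
  structure(
    c(results, list(
      final_recommendation = if (is.na(final_recommendation)) {
        NA_character_
      } else {
        as.character(final_recommendation)
      },
      comments = comments,
      final_comment = final_comment
    )),
    class = "hss_notes"
  )
}

as_notes <- function(x) {
  if (inherits(x, "hss_notes")) {
    return(x)
  }
  if (is.null(x)) {
    return(technician_notes())
  }
  if (is.list(x)) {
    args <- x[intersect(names(x),
                        c(NOTE_SLOTS, "final_recommendation", "final_comment"))]
    args <- lapply(args, function(v) if (is.null(v)) NA else v)
    if (!is.null(x$comments)) {
      args$comments <- x$comments
    }
    return(do.call(technician_notes, args))
  }
  hss_abort("cannot interpret technician notes", "hss_notes_error")
}

#' Check technician notes for completeness
#'
#' A complete note set has all six per-ear results and a final
#' recommendation.
#'
#' @param notes An [technician_notes()] object (or `NULL`).
#' @return A list with `complete` (flag) and `missing` (character vector of
#'   empty slots).
#' @export
notes_completeness <- function(notes) {
  notes <- as_notes(notes)
  slots <- c(NOTE_SLOTS, "final_recommendation")
  missing <- slots[vapply(slots, function(s) is.na(notes[[s]]), logical(1))]
  list(complete = length(missing) == 0, missing = missing)
}

#' @export
print.hss_notes <- function(x, ...) {
  comp <- notes_completeness(x)
  cat("<technician notes: ",
      if (comp$complete) "complete" else paste0(length(comp$missing), " slot(s) missing"),
      ">\n", sep = "")
  for (slot in c(NOTE_SLOTS, "final_recommendation")) {
    cat(sprintf("  %-22s %s\n", slot, x[[slot]]))
  }
  invisible(x)
}
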
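# Internal helpers: error signalling, private RNG streams, injectable clocks,
# and backstory template rendering.

hss_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "hss_error"), ...)
}

#' Path to a bundled configuration or fixture file
#'
#' Resolves a file shipped under the package's `extdata` directory (the default
#' roster, name pool, protocol, normative ranges, schemas and demo action
#' script).
#'
#' @param file File name, e.g. `"roster.json"`. With no argument, lists the
#'   available files.
#' @return A file path, or a character vector of file names.
#' @export
#' @examples
#' hss_file()
#' hss_file("roster.json")
hss_file <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "hearscreen")))
  }
  path <- system.file("extdata", file, package = "hearscreen")
  if (!nzchar(path)) {
    hss_abort(paste0("no bundled file '", file, "'"), "hss_validation_error")
  }
  path
}

# A self-contained uniform RNG stream that never disturbs the caller's
# .Random.seed. Each session owns one, so scripted replays are deterministic.
make_rng <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    hss_abort("rng seed must be a single number", "hss_validation_error")
  }
  rng <- new.env(parent = emptyenv())
  rng$seed <- as.integer(seed)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(rng$seed)
  rng$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  rng$unif <- function(n = 1) {
    outer <- get0(".Random.seed", envir = globalenv())
    assign(".Random.seed", rng$state, envir = globalenv())
    u <- stats::runif(n)
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(outer)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", outer, envir = globalenv())
    }
    u
  }
  class(rng) <- "hss_rng"
  rng
}

#' Clocks for session timestamping
#'
#' Sessions read timestamps through an injected clock function so that
#' durations are testable. `system_clock()` returns the wall clock;
#' `step_clock()` returns a synthetic clock that advances by a fixed number of
#' seconds on every call, starting at `start`.
#'
#' @param start POSIXct start time of the synthetic clock.
#' @param step Seconds the synthetic clock advances per call.
#' @return A zero-argument function returning a POSIXct timestamp.
#' @export
system_clock <- function() {
  function() Sys.time()
}

#' @rdname system_clock
#' @export
step_clock <- function(start = as.POSIXct("2024-01-01 09:00:00", tz = "UTC"),
                       step = 1) {
  t <- start - step
  function() {
    t <<- t + step
    t
  }
}

# Literal {placeholder} substitution for case-history templates. Deliberately
# not glue(): templates come from user-editable config files and must not
# evaluate code.
render_template <- function(template, values) {
  out <- template
  for (key in names(values)) {
    out <- gsub(paste0("{", key, "}"), values[[key]], out, fixed = TRUE)
  }
  out
}

pronoun_set <- function(sex) {
  switch(sex,
    female = list(subject = "she", object = "her", possessive = "her"),
    male   = list(subject = "he", object = "him", possessive = "his"),
    hss_abort(paste0("unknown sex '", sex, "'"), "hss_validation_error")
  )
}

capitalize <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

iso_time <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%OS3%z")
}

parse_iso_time <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
}
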
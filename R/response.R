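# Psychometric response model: the virtual subject's hand-raise behaviour.

#' Psychometric response parameters
#'
#' Parameters of the subject's detection behaviour for a presented tone. With
#' `slope = 0` the subject is a deterministic step listener: they respond
#' exactly when the presentation level reaches their threshold. With
#' `slope > 0` responses follow a guess/lapse-adjusted logistic psychometric
#' function, which emulates the threshold inconsistency real screening
#' subjects show near their threshold.
#'
#' @param slope Logistic slope parameter in dB (>= 0). 0 selects the
#'   deterministic step model.
#' @param guess Probability in `[0, 1)` of a spontaneous response to an
#'   inaudible tone (false alarm rate).
#' @param lapse Probability in `[0, 1)` of missing a clearly audible tone
#'   (inattention rate).
#' @return An object of class `hss_response_params`.
#' @export
#' @examples
#' response_params()            # deterministic listener
#' response_params(slope = 3)   # inconsistent near threshold
response_params <- function(slope = 0, guess = 0, lapse = 0) {
  for (v in list(slope = slope, guess = guess, lapse = lapse)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      hss_abort("response parameters must be single numbers",
                "hss_validation_error")
    }
  }
  if (slope < 0) {
    hss_abort("slope must be >= 0 dB", "hss_validation_error")
  }
  if (guess < 0 || guess >= 1 || lapse < 0 || lapse >= 1) {
    hss_abort("guess and lapse rates must lie in [0, 1)",
              "hss_validation_error")
  }
  if (guess + lapse >= 1) {
    hss_abort("guess + lapse must be < 1", "hss_validation_error")
  }
  structure(
    list(slope = slope, guess = guess, lapse = lapse),
    class = "hss_response_params"
  )
}

#' @export
print.hss_response_params <- function(x, ...) {
  cat(sprintf("<response params: slope %g dB, guess %g, lapse %g>\n",
              x$slope, x$guess, x$lapse))
  invisible(x)
}

#' Probability that the subject responds to a tone
#'
#' For a step listener (`slope = 0`) the probability is 1 when
#' `level >= threshold` (a tone at the subject's threshold is, by definition,
#' audible) and `guess` otherwise. For `slope > 0` it is
#' `guess + (1 - guess - lapse) / (1 + exp(-(level - threshold)/slope))`,
#' which is nondecreasing in `level` and reduces to the step model as the
#' slope shrinks.
#'
#' @param level Presentation level in dB HL (vectorised).
#' @param threshold The subject's threshold at the tested frequency, dB HL.
#' @param params An [response_params()] object.
#' @return Response probability, same length as `level`.
#' @export
#' @examples
#' response_probability(20, threshold = 15)              # 1: audible
#' response_probability(20, threshold = 40)              # 0: inaudible
#' response_probability(30, 30, response_params(slope = 5))  # 0.5 at midpoint
response_probability <- function(level, threshold,
                                 params = response_params()) {
  params <- as_response_params(params)
  if (params$slope == 0) {
    ifelse(level >= threshold, 1, params$guess)
  } else {
    params$guess + (1 - params$guess - params$lapse) *
      stats::plogis((level - threshold) / params$slope)
  }
}

#' Draw a single hand-raise response
#'
#' Bernoulli draw with probability [response_probability()], taken from a
#' session-owned random stream so that identical seeds reproduce identical
#' response sequences.
#'
#' @inheritParams response_probability
#' @param rng A session RNG stream (internal; created with a session's seed).
#' @return `TRUE` if the subject raises their hand.
#' @keywords internal
simulate_response <- function(level, threshold, params, rng) {
  p <- response_probability(level, threshold, params)
  u <- rng$unif(1)
  p >= 1 || u < p
}

as_response_params <- function(x) {
  if (inherits(x, "hss_response_params")) {
    return(x)
  }
  if (is.null(x)) {
    return(response_params())
  }
  if (is.list(x)) {
    return(response_params(
      slope = x$slope %||% 0,
      guess = x$guess %||% 0,
      lapse = x$lapse %||% 0
    ))
  }
  hss_abort("cannot interpret response parameters", "hss_validation_error")
}
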
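# ggplot2 figures: audiograms and cohort error-rate summaries.

#' Plot a patient's audiogram
#'
#' Thresholds per ear on the conventional audiogram axes (frequency on a log
#' scale, level increasing downwards), with the screening level drawn as a
#' dashed reference line: any threshold below that line would not be heard at
#' the screening level.
#'
#' @param patient An `hss_patient` or `hss_presentation`.
#' @param protocol An [protocol_config()]; supplies the screening-level line.
#' @return A ggplot object.
#' @export
plot_audiogram <- function(patient, protocol = protocol_config()) {
  if (inherits(patient, "hss_presentation")) {
    patient <- patient$base
  }
  df <- purrr::map_dfr(EARS, function(ear) {
    thr <- patient$audiogram[[ear]]$thresholds
    tibble(
      ear = ear,
      frequency = as.numeric(names(thr)),
      threshold = unname(thr)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$threshold,
                                   colour = .data$ear, shape = .data$ear)) +
    ggplot2::geom_hline(yintercept = protocol$screening_level,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_log10(breaks = device_frequencies(),
                           labels = device_frequencies()) +
    ggplot2::scale_y_reverse(limits = c(120, -10)) +
    ggplot2::scale_shape_manual(values = c(left = 4, right = 1)) +
    ggplot2::labs(
      title = paste0("Audiogram: ", patient$id),
      x = "Frequency (Hz)", y = "Threshold (dB HL)",
      colour = "Ear", shape = "Ear"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn cohort_summary Bar chart of per-item error rates across the
#'   cohort.
#' @param object An `hss_cohort`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hss_cohort <- function(object, ...) {
  df <- object$item_error_rates
  df$item <- factor(df$item, levels = rev(GRADE_ITEMS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$error_rate, y = .data$item)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Per-item error rates (%d sessions)",
                      object$n_sessions),
      x = "Error rate", y = NULL
    ) +
    ggplot2::theme_minimal()
}
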
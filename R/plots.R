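#' Plot a contrast time series
#'
#' Blood-flow trace over time, with segment shading when the series came
#' from a scenario with a known truth table.
#'
#' @param object A `contrast_series` tibble.
#' @param value One of `"rbfi"`, `"bfi"`, `"kappa_c_sq"`, `"kappa_m_sq"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contrast_series
#' @export
autoplot.contrast_series <- function(object, value = c("rbfi", "bfi",
                                                       "kappa_c_sq",
                                                       "kappa_m_sq"), ...) {
  value <- match.arg(value)
  if (!value %in% names(object)) {
    value <- if ("bfi" %in% names(object)) "bfi" else "kappa_c_sq"
  }
  lab <- c(rbfi = "relative BFi", bfi = "BFi = 1 / κ_c²",
           kappa_c_sq = "corrected κ²",
           kappa_m_sq = "measured κ²")[[value]]
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_s, y = .data[[value]])) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "time (s)", y = lab) +
    ggplot2::theme_minimal()
}

#' Plot a Welch PSD estimate
#'
#' @param object A `psd_estimate` tibble.
#' @param log_power Plot power on a log10 scale (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psd_estimate
#' @export
autoplot.psd_estimate <- function(object, log_power = TRUE, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$frequency_hz,
                                    y = .data$power)) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::labs(x = "frequency (Hz)", y = "power spectral density") +
    ggplot2::theme_minimal()
  if (log_power) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot an envelope trend
#'
#' Series with its upper/lower peak envelopes and their midline trend.
#'
#' @param object An `envelope_trend` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot envelope_trend
#' @export
autoplot.envelope_trend <- function(object, ...) {
  xvar <- if ("time_s" %in% names(object)) "time_s" else "index"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]])) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), colour = "#b2182b",
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), colour = "#b2182b",
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$trend), colour = "black") +
    ggplot2::labs(x = if (xvar == "time_s") "time (s)" else "sample",
                  y = "value") +
    ggplot2::theme_minimal()
}

#' Plot contrast versus flow index
#'
#' Inverse squared contrast against the flow index from a
#' [contrast_vs_flow_curve()] sweep, with the least-squares line.
#'
#' @param curve A tibble from [contrast_vs_flow_curve()].
#' @return A ggplot object.
#' @export
plot_flow_linearity <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$alpha_db,
                                      y = .data$inv_kappa_sq)) +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = expression(alpha * D[b] ~ (mm^2 / s)),
                  y = expression(1 / kappa^2)) +
    ggplot2::theme_minimal()
}
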
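#' Plot a recording trace
#'
#' Time course with the light epoch shaded.
#'
#' @param object An [acr_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.acr_trace <- function(object, ...) {
  unit <- attr(object, "unit")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$time, .data$value))
  if (!is.na(attr(object, "light_on"))) {
    p <- p + ggplot2::annotate(
      "rect", xmin = attr(object, "light_on"),
      xmax = attr(object, "light_off"), ymin = -Inf, ymax = Inf,
      fill = "#9ecae1", alpha = 0.3
    )
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)",
                  y = paste0(if (unit == "mV") "membrane voltage ("
                             else "current (", unit, ")")) +
    ggplot2::theme_minimal()
}

#' Plot an I-V curve
#'
#' Current metric vs LJP-corrected voltage per bath condition, with the
#' zero-current level marked.
#'
#' @param object An `acr_iv` from [build_iv()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.acr_iv <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$v_corr, .data$current,
                               colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "corrected voltage (mV)",
                  y = paste0(attr(object, "metric"), " current (pA)"),
                  colour = "bath") +
    ggplot2::theme_minimal()
}

#' Plot an action spectrum
#'
#' Normalized sensitivity with the fitted pigment template overlaid.
#'
#' @param object An `acr_spectrum` from [action_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.acr_spectrum <- function(object, ...) {
  spec <- object$spectrum
  grid <- tibble::tibble(
    wavelength = seq(min(spec$wavelength), max(spec$wavelength),
                     length.out = 200)
  )
  grid$fit <- pigment_template(grid$wavelength, object$lambda_max,
                               family = object$family)
  ggplot2::ggplot(spec, ggplot2::aes(.data$wavelength,
                                     .data$sensitivity)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fit), colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$lambda_max, linetype = 2,
                        colour = "#3182bd") +
    ggplot2::labs(x = "wavelength (nm)", y = "normalized sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot spike-suppression metrics
#'
#' Normalized per-stimulus response amplitudes around the light pulse.
#'
#' @param object An `acr_spike_metrics` from [spike_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.acr_spike_metrics <- function(object, ...) {
  ggplot2::ggplot(object$per_stimulus,
                  ggplot2::aes(.data$stim_time, .data$norm_amplitude,
                               colour = .data$suppressed)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "#de2d26")) +
    ggplot2::labs(x = "stimulus time (ms)",
                  y = "normalized response amplitude",
                  colour = "suppressed") +
    ggplot2::theme_minimal()
}
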
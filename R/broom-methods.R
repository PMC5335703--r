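#' Tidy a light-off decay fit
#'
#' @param x An `acr_decay_fit` from [fit_exponential_decay()].
#' @param ... Unused.
#' @return A tibble with one row per quantity (`tau`, `amplitude`,
#'   `baseline`, `t_half`, `t90`) and columns `term`, `estimate`,
#'   `unit`.
#' @exportS3Method generics::tidy
tidy.acr_decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("tau", "amplitude", "baseline", "t_half", "t90"),
    estimate = c(x$tau, x$amplitude, x$baseline, x$t_half, x$t90),
    unit = c("ms", "pA", "pA", "ms", "ms")
  )
}

#' @rdname tidy.acr_decay_fit
#' @exportS3Method generics::glance
glance.acr_decay_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, t_half = x$t_half, t90 = x$t90,
                 sigma = x$sigma, n = x$n)
}

#' Tidy an intensity-response fit
#'
#' @param x An `acr_intensity_fit` from [intensity_response_fit()].
#' @param ... Unused.
#' @return One row per parameter (`r_max`, `i50`).
#' @exportS3Method generics::tidy
tidy.acr_intensity_fit <- function(x, ...) {
  tibble::tibble(term = c("r_max", "i50"),
                 estimate = c(x$r_max, x$i50),
                 unit = c("pA", "mW/mm^2"))
}

#' @rdname tidy.acr_intensity_fit
#' @exportS3Method generics::glance
glance.acr_intensity_fit <- function(x, ...) {
  tibble::tibble(r_max = x$r_max, i50 = x$i50, sigma = x$sigma,
                 n = x$n, i50_lower_bound_flag = x$i50_lower_bound_flag)
}

#' Tidy an action spectrum
#'
#' @param x An `acr_spectrum` from [action_spectrum()].
#' @param ... Unused.
#' @return `tidy()`: the normalized per-wavelength spectrum;
#'   `glance()`: one row with `lambda_max`, `reliable`, `family`.
#' @exportS3Method generics::tidy
tidy.acr_spectrum <- function(x, ...) {
  x$spectrum
}

#' @rdname tidy.acr_spectrum
#' @exportS3Method generics::glance
glance.acr_spectrum <- function(x, ...) {
  tibble::tibble(lambda_max = x$lambda_max, reliable = x$reliable,
                 family = x$family)
}

#' Tidy spike-suppression metrics
#'
#' @param x An `acr_spike_metrics` from [spike_analysis()].
#' @param ... Unused.
#' @return `tidy()`: the per-stimulus table; `glance()`: one row with
#'   the suppressed count and totals.
#' @exportS3Method generics::tidy
tidy.acr_spike_metrics <- function(x, ...) {
  x$per_stimulus
}

#' @rdname tidy.acr_spike_metrics
#' @exportS3Method generics::glance
glance.acr_spike_metrics <- function(x, ...) {
  tibble::tibble(
    suppressed_count = x$suppressed_count,
    n_stimuli = nrow(x$per_stimulus),
    n_spikes_light = sum(x$per_stimulus$fired_light),
    n_spikes_control = sum(x$per_stimulus$fired_control),
    baseline_n = x$baseline_n
  )
}
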
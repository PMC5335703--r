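#' Peak and stationary photocurrent of a light pulse
#'
#' Sign-aware extrema: the peak is the sample of largest magnitude
#' within the light epoch (after a settling margin that skips the
#' acquisition-filter onset transient), returned with its sign; the
#' stationary current is the mean over the final fraction of the epoch
#' ("near the end of the illumination period").
#'
#' @param trace An [acr_trace()] with an annotated light epoch.
#' @param stationary_frac Final fraction of the epoch averaged for the
#'   stationary level (default 0.1).
#' @param settle_ms Initial margin excluded from the peak search, ms.
#' @param min_epoch_ms Minimum epoch length for a stationary estimate.
#' @return A one-row tibble with `i_peak` and `i_stationary` (pA).
#' @export
peak_and_stationary <- function(trace, stationary_frac = 0.1,
                                settle_ms = 2, min_epoch_ms = 200) {
  ep <- light_epoch(trace)
  if (diff(ep) < min_epoch_ms) {
    stop("light epoch shorter than ", min_epoch_ms,
         " ms: stationary level undefined", call. = FALSE)
  }
  lit <- trace$time >= ep[1] + settle_ms & trace$time <= ep[2]
  seg <- trace$value[lit]
  i_peak <- seg[which.max(abs(seg))]
  tail_start <- ep[2] - stationary_frac * diff(ep)
  i_stat <- mean(trace$value[trace$time >= tail_start & trace$time <= ep[2]])
  tibble::tibble(i_peak = i_peak, i_stationary = i_stat)
}

#' Percent inactivation during sustained illumination
#'
#' `100 * (|I_peak| - |I_stationary|) / |I_peak|`: the decline from peak
#' to stationary current during a 1-s light pulse, the quantity that
#' ranges from ~12.5% to ~83.6% across the ACR family.
#'
#' @param i_peak Peak current (pA), or an [acr_trace()] from which both
#'   metrics are extracted via [peak_and_stationary()].
#' @param i_stationary Stationary current, pA (ignored when `i_peak` is
#'   a trace).
#' @return Percent inactivation.
#' @export
inactivation_percent <- function(i_peak, i_stationary = NULL) {
  if (inherits(i_peak, "acr_trace")) {
    ps <- peak_and_stationary(i_peak)
    i_stationary <- ps$i_stationary
    i_peak <- ps$i_peak
  }
  if (abs(i_peak) == 0) {
    stop("zero peak current: inactivation undefined", call. = FALSE)
  }
  100 * (abs(i_peak) - abs(i_stationary)) / abs(i_peak)
}

#' Mean photocurrent over the illumination period
#'
#' Arithmetic mean of the current over the full light epoch — the metric
#' used for reversal-potential shifts because it averages noise over the
#' entire 1-s illumination.
#'
#' @param trace An [acr_trace()] with an annotated light epoch.
#' @return Mean current, pA.
#' @export
mean_photocurrent <- function(trace) {
  ep <- light_epoch(trace)
  mean(trace$value[trace$time >= ep[1] & trace$time <= ep[2]])
}

#' Initial-slope response to a weak light pulse
#'
#' Mean current over an early post-onset window (default 5-15 ms), the
#' response measure used for action spectra because it stays linear in
#' light intensity.  The window is accepted as "close to linear rise"
#' when the RMS residual of a straight-line fit is small relative to the
#' rise covered by the window (`|slope| * width`); a saturating response
#' that flattens inside the window fails this test, the window end is
#' then shortened in 1-ms steps, and if no sub-window is linear the
#' result carries a `nonlinear` flag.
#'
#' @param trace An [acr_trace()] with an annotated light epoch.
#' @param window `c(start, end)` in ms after light onset; must lie
#'   within the light epoch.
#' @param curvature_tol Tolerated RMS deviation from linearity relative
#'   to the rise spanned by the window.
#' @return A one-row tibble with `response` (pA), `window_start`,
#'   `window_end` (ms after onset) and `nonlinear` (logical).
#' @export
initial_slope_response <- function(trace, window = c(5, 15),
                                   curvature_tol = 0.1) {
  ep <- light_epoch(trace)
  if (window[1] < 0 || ep[1] + window[2] > ep[2]) {
    stop("response window outside the light epoch", call. = FALSE)
  }
  w_end <- window[2]
  nonlinear <- FALSE
  repeat {
    sel <- trace$time >= ep[1] + window[1] & trace$time <= ep[1] + w_end
    seg <- trace[sel, , drop = FALSE]
    fit <- stats::lm(value ~ time, data = seg)
    rise <- abs(stats::coef(fit)[2]) * (w_end - window[1])
    rel <- sqrt(mean(stats::resid(fit)^2)) / max(rise, 1e-300)
    if (rel <= curvature_tol) break
    if (w_end - 1 <= window[1] + 2) {
      nonlinear <- TRUE
      break
    }
    w_end <- w_end - 1
  }
  tibble::tibble(response = mean(seg$value),
                 window_start = window[1], window_end = w_end,
                 nonlinear = nonlinear || w_end < window[2])
}
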
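#' Functional-diversity summary across channel variants
#'
#' One row per variant with the three axes on which the ACR family
#' varies: peak photocurrent amplitude at -60 mV holding (the reporting
#' convention for amplitudes), off-decay rate (reciprocal of the
#' 50%-decay time after light-off, s^-1) and wavelength of maximal
#' sensitivity from the action-spectrum fit.  Variants with a missing
#' stage input are kept but flagged incomplete.
#'
#' @param variants Named list; each element is a list with components
#'   `trace` (an [acr_trace()] recorded at -60 mV) and `scans` (a
#'   spectral-scan table for [action_spectrum()]).  Missing components
#'   yield `NA` for the corresponding column.
#' @return A tibble with columns `variant`, `peak_pa`, `decay_rate`,
#'   `lambda_max`, `complete`.
#' @export
diversity_summary <- function(variants) {
  if (length(variants) == 0) {
    return(tibble::tibble(variant = character(), peak_pa = numeric(),
                          decay_rate = numeric(), lambda_max = numeric(),
                          complete = logical()))
  }
  stopifnot(!is.null(names(variants)))
  purrr::imap_dfr(variants, function(v, nm) {
    peak <- decay <- lmax <- NA_real_
    if (!is.null(v$trace)) {
      peak <- peak_and_stationary(v$trace)$i_peak
      decay <- half_decay_time(v$trace)$rate
    }
    if (!is.null(v$scans)) {
      lmax <- action_spectrum(v$scans)$lambda_max
    }
    tibble::tibble(variant = nm, peak_pa = peak, decay_rate = decay,
                   lambda_max = lmax,
                   complete = !is.null(v$trace) && !is.null(v$scans))
  })
}
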
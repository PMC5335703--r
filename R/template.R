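#' Visual-pigment spectral sensitivity template
#'
#' Relative spectral sensitivity of a rhodopsin pigment with maximum at
#' `lambda_max`.  The default family is the Govardovskii et al. (2000,
#' Vis Neurosci 17:509) A1 alpha-band nomogram, the standard "continuous
#' approximation" for retinal-based pigments; a Gaussian in inverse
#' wavelength (constant bandwidth in energy) is available as an
#' alternative.  Both families are anchored so that the template equals
#' exactly 1 at `lambda_max` and is unimodal with its maximum there: for
#' the nomogram, whose analytic peak sits a fraction of a nanometre away
#' from its nominal `lambda_max`, the wavelength axis is rescaled by the
#' numerically located peak before normalisation.
#'
#' @param lambda Wavelength(s), nm; must lie in `range`.
#' @param lambda_max Wavelength of maximal sensitivity, nm (300-700).
#' @param family `"govardovskii"` (default) or `"gaussian"`.
#' @param range Validity range of the template, nm.
#' @param gaussian_sigma Width of the Gaussian alternative in inverse
#'   wavelength (nm^-1); the default reproduces a typical ~100 nm FWHM
#'   at 500 nm.
#' @return Relative sensitivity in (0, 1], same length as `lambda`.
#' @examples
#' pigment_template(470, 515)
#' @export
pigment_template <- function(lambda, lambda_max,
                             family = c("govardovskii", "gaussian"),
                             range = c(300, 800),
                             gaussian_sigma = 2.4e-4) {
  family <- match.arg(family)
  if (lambda_max < 300 || lambda_max > 700) {
    stop("lambda_max must lie in [300, 700] nm", call. = FALSE)
  }
  if (any(lambda < range[1] | lambda > range[2])) {
    stop("wavelength outside template validity range [",
         range[1], ", ", range[2], "] nm", call. = FALSE)
  }
  if (family == "gaussian") {
    return(exp(-((1 / lambda - 1 / lambda_max) / gaussian_sigma)^2))
  }
  peak <- .gov_peak(lambda_max)
  .gov_alpha(lambda * peak / lambda_max, lambda_max) /
    .gov_alpha(peak, lambda_max)
}

# Govardovskii A1 alpha-band, un-normalised
.gov_alpha <- function(lambda, lambda_max) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
         exp(-14.9 * (1.104 - x)) + 0.674)
}

# wavelength of the analytic maximum of the alpha-band (cached per call)
.gov_peak <- function(lambda_max) {
  stats::optimize(function(l) .gov_alpha(l, lambda_max),
                  interval = lambda_max + c(-25, 25), maximum = TRUE,
                  tol = 1e-6)$maximum
}
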
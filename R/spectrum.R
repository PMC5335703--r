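#' Action spectrum from raw spectral-scan responses
#'
#' Implements the standard photon-counting correction: per wavelength
#' the forward- and reverse-scan responses are averaged (cancelling a
#' linear sensitivity drift to first order), divided by the photon flux
#' density delivered at that wavelength (quantum-density correction) and
#' normalized to the maximum.  The wavelength of maximal sensitivity is
#' estimated by least-squares fit of a pigment spectral template
#' ([pigment_template()]); when the corrected spectrum is too flat to
#' constrain a peak the fit is flagged unreliable.
#'
#' @param scans A tibble with columns `wavelength`, `response` and
#'   either `power` (mW/mm^2) or a `calibration`; typically an
#'   `acr_spectral_scan` from [synthesize_spectral_responses()].
#'   A `direction` column, when present, is averaged over.
#' @param calibration Optional per-wavelength photon flux: a data frame
#'   with `wavelength` and `flux` columns.  Every scanned wavelength
#'   must be covered.  Defaults to [photon_flux_density()] applied to
#'   the `power` column.
#' @param family Template family passed to [pigment_template()].
#' @param flat_tol Relative range of the corrected spectrum below which
#'   the peak fit is flagged unreliable.
#' @return An object of class `acr_spectrum`: list with `spectrum`
#'   (tibble `wavelength`, `sensitivity` normalized to 1, per-direction
#'   raw means), `lambda_max` (nm), `reliable` (logical), `family`.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
action_spectrum <- function(scans, calibration = NULL,
                            family = "govardovskii", flat_tol = 0.1) {
  tab <- tibble::as_tibble(scans)
  stopifnot(all(c("wavelength", "response") %in% names(tab)))
  if (!"direction" %in% names(tab)) tab$direction <- "forward"
  if (is.null(calibration)) {
    if (!"power" %in% names(tab)) {
      stop("no calibration given and no power column to derive one from",
           call. = FALSE)
    }
    tab$flux <- photon_flux_density(tab$power, tab$wavelength)
  } else {
    idx <- match(tab$wavelength, calibration$wavelength)
    if (anyNA(idx)) {
      stop("calibration missing wavelength(s): ",
           paste(unique(tab$wavelength[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    tab$flux <- calibration$flux[idx]
  }
  per_dir <- tab |>
    dplyr::group_by(.data$wavelength, .data$direction) |>
    dplyr::summarise(raw = mean(abs(.data$response)), .groups = "drop")
  spec <- per_dir |>
    tidyr::pivot_wider(names_from = "direction", values_from = "raw",
                       names_prefix = "raw_") |>
    dplyr::left_join(
      tab |> dplyr::distinct(.data$wavelength, .data$flux),
      by = "wavelength"
    )
  raw_cols <- grep("^raw_", names(spec), value = TRUE)
  spec$sensitivity <- rowMeans(as.matrix(spec[raw_cols])) / spec$flux
  spec$sensitivity <- spec$sensitivity / max(spec$sensitivity)
  spec <- dplyr::arrange(spec, .data$wavelength)

  rng <- range(spec$wavelength)
  flat <- (max(spec$sensitivity) - min(spec$sensitivity)) /
    max(spec$sensitivity) < flat_tol
  sse <- function(lm_) {
    tt <- pigment_template(spec$wavelength, lm_, family = family)
    a <- sum(spec$sensitivity * tt) / sum(tt^2)
    sum((spec$sensitivity - a * tt)^2)
  }
  grid <- seq(max(rng[1] - 30, 310), min(rng[2] + 30, 690), by = 2)
  best <- grid[which.min(vapply(grid, sse, numeric(1)))]
  opt <- stats::optimize(sse, interval = best + c(-4, 4))
  lambda_max <- opt$minimum
  structure(
    list(spectrum = spec, lambda_max = lambda_max,
         reliable = !flat, family = family),
    class = "acr_spectrum"
  )
}

#' @export
print.acr_spectrum <- function(x, ...) {
  cat("<acr_spectrum> lambda_max =", signif(x$lambda_max, 4), "nm (",
      x$family, if (!x$reliable) ", UNRELIABLE: flat spectrum" else "",
      ")\n", sep = "")
  invisible(x)
}

#' Hyperbolic intensity-response fit
#'
#' Least-squares fit of the saturation hyperbola
#' `R = R_max * I / (I + I50)` to response-vs-intensity data, the
#' functional form implied by the single-photoreceptor gating model.
#' When the data show no curvature (all points in the linear range) the
#' fitted I50 is only a lower bound and is flagged as such.
#'
#' @param data A data frame with columns `intensity` (mW/mm^2) and
#'   `response`.
#' @return An object of class `acr_intensity_fit` with `r_max`, `i50`,
#'   `sigma`, `n`, `i50_lower_bound_flag`.  Supports tidy()/glance().
#' @export
intensity_response_fit <- function(data) {
  stopifnot(all(c("intensity", "response") %in% names(data)))
  data <- data[order(data$intensity), , drop = FALSE]
  if (length(unique(data$intensity)) < 4) {
    stop("need >= 4 distinct intensities", call. = FALSE)
  }
  sgn <- sign(data$response[which.max(abs(data$response))])
  y <- abs(data$response)
  i <- data$intensity
  i50_0 <- stats::median(i)
  fit <- try(stats::nls(y ~ rmax * i / (i + i50),
                        start = list(rmax = max(y), i50 = i50_0),
                        control = stats::nls.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    # zero-residual (exact) data can defeat nls; direct least squares
    obj <- function(p) sum((y - p[1] * i / (i + p[2]))^2)
    co <- stats::optim(c(max(y), i50_0), obj)$par
    names(co) <- c("rmax", "i50")
    sig <- sqrt(obj(co) / max(1, length(y) - 2))
  } else {
    co <- stats::coef(fit)
    sig <- stats::sigma(fit)
  }
  flag <- unname(co["i50"]) > 10 * max(i)
  structure(
    list(r_max = sgn * unname(co["rmax"]), i50 = unname(co["i50"]),
         sigma = sig, n = nrow(data),
         i50_lower_bound_flag = flag),
    class = "acr_intensity_fit"
  )
}

#' @export
print.acr_intensity_fit <- function(x, ...) {
  cat("<acr_intensity_fit> R_max =", signif(x$r_max, 4), " I50 =",
      signif(x$i50, 4), "mW/mm^2",
      if (x$i50_lower_bound_flag) " (lower bound: no curvature)" else "",
      "\n")
  invisible(x)
}
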
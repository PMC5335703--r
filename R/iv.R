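#' Build an I-V curve from per-voltage traces
#'
#' Corrects command voltages for the liquid-junction potential
#' (`v_corr = v_command - ljp`) and extracts one current metric per
#' trace: `"mean"` (average over the whole illumination period, the
#' metric used for reversal-potential shifts), `"peak"` or
#' `"stationary"`.
#'
#' @param family An `acr_iv_family` from [synthesize_iv_family()], or
#'   any tibble with columns `v_command`, `trace` (and optionally
#'   `condition`, `ljp`).
#' @param metric Current metric to extract.
#' @param ljp Optional LJP override, mV (defaults to the family's `ljp`
#'   column, else 0).
#' @return A tibble of class `acr_iv` with columns `condition`,
#'   `v_command`, `v_corr`, `current`, plus a `metric` attribute.
#' @export
build_iv <- function(family, metric = c("mean", "peak", "stationary"),
                     ljp = NULL) {
  metric <- match.arg(metric)
  tab <- tibble::as_tibble(family)
  if (!"condition" %in% names(tab)) tab$condition <- "standard"
  if (!is.null(ljp)) {
    tab$ljp <- ljp
  } else if (!"ljp" %in% names(tab)) {
    tab$ljp <- 0
  }
  if (any(duplicated(tab[c("condition", "v_command")]))) {
    stop("duplicate command voltages within a condition", call. = FALSE)
  }
  extract <- switch(metric,
    mean = mean_photocurrent,
    peak = function(tr) peak_and_stationary(tr)$i_peak,
    stationary = function(tr) peak_and_stationary(tr)$i_stationary
  )
  out <- tab |>
    dplyr::mutate(v_corr = .data$v_command - .data$ljp,
                  current = purrr::map_dbl(.data$trace, extract)) |>
    dplyr::select(dplyr::all_of(c("condition", "v_command", "v_corr",
                                  "current"))) |>
    dplyr::arrange(.data$condition, .data$v_corr)
  structure(out, class = c("acr_iv", class(out)), metric = metric)
}

#' Reversal potential from an I-V curve
#'
#' Linear interpolation between the first pair of voltages (scanning
#' from the most negative) at which the current metric changes sign.
#' With noise the curve can cross zero more than once; the first
#' crossing is the documented tie-break.
#'
#' @param iv An `acr_iv` from [build_iv()].
#' @return A tibble of class `acr_reversal` with one row per condition:
#'   `condition`, `e_rev` (mV), `metric`.
#' @export
reversal_potential <- function(iv) {
  stopifnot(inherits(iv, "acr_iv"))
  metric <- attr(iv, "metric")
  out <- iv |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(e_rev = .interp_reversal(.data$v_corr, .data$current),
                     .groups = "drop") |>
    dplyr::mutate(metric = metric)
  structure(out, class = c("acr_reversal", class(out)))
}

.interp_reversal <- function(v, i) {
  ord <- order(v)
  v <- v[ord]; i <- i[ord]
  if (any(i == 0)) return(v[which(i == 0)[1]])
  s <- sign(i)
  cross <- which(s[-1] != s[-length(s)])
  if (length(cross) == 0) {
    stop("no sign change across the voltage grid: reversal out of range",
         call. = FALSE)
  }
  k <- cross[1]
  v[k] + (0 - i[k]) * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
}

#' Reversal-potential shift under anion substitution
#'
#' Signed shift `E_r(standard) - E_r(substituted)`, the convention in
#' which replacement of permeant chloride by a non-permeant anion gives
#' a negative shift for an anion-selective channel.
#'
#' @param standard,substituted One-row `acr_reversal` results (or the
#'   single two-condition result of [reversal_potential()], in which
#'   case `substituted` is omitted and conditions `"standard"` and
#'   `"substituted"` are used).
#' @return A tibble with `e_rev_standard`, `e_rev_substituted`,
#'   `delta_e_rev` (mV) and `metric`.
#' @export
reversal_shift <- function(standard, substituted = NULL) {
  if (is.null(substituted)) {
    stopifnot(inherits(standard, "acr_reversal"))
    tab <- standard
    std <- tab[tab$condition == "standard", ]
    sub <- tab[tab$condition == "substituted", ]
    if (nrow(std) != 1 || nrow(sub) != 1) {
      stop("expected conditions 'standard' and 'substituted'", call. = FALSE)
    }
  } else {
    std <- standard; sub <- substituted
  }
  if (!identical(std$metric[1], sub$metric[1])) {
    stop("metric mismatch between conditions: ", std$metric[1], " vs ",
         sub$metric[1], call. = FALSE)
  }
  tibble::tibble(e_rev_standard = std$e_rev[1],
                 e_rev_substituted = sub$e_rev[1],
                 delta_e_rev = std$e_rev[1] - sub$e_rev[1],
                 metric = std$metric[1])
}

#' Permeability ratio from a reversal-potential shift
#'
#' Inverts the GHK prediction: finds the relative permeability
#' `P_sub/P_Cl` of the substituting anion for which the predicted shift
#' `E_r(standard) - E_r(substituted)` equals the observed one.  A shift
#' equal to the zero-permeability prediction returns 0; a zero shift
#' returns 1 (the substituting anion is indistinguishable from Cl-).
#'
#' @param delta_e_rev Observed shift, mV (standard minus substituted),
#'   or the tibble returned by [reversal_shift()].
#' @param sol_in Pipette [solution()].
#' @param sol_standard,sol_substituted The two bath [solution()]s.
#' @param sub_ion Name of the substituting anion (default `"Asp"`).
#' @param upper Upper bracket for the ratio.
#' @param boundary_tol Shifts overshooting the zero-permeability floor
#'   by at most this much (mV, measurement error) clamp to ratio 0.
#' @return A tibble with `ratio`, `observed_shift`, `predicted_shift`,
#'   `residual`.
#' @export
fit_permeability_ratio <- function(delta_e_rev,
                                   sol_in = pipette_solution(),
                                   sol_standard = standard_bath(),
                                   sol_substituted = aspartate_bath(),
                                   sub_ion = "Asp", upper = 100,
                                   boundary_tol = 0.5) {
  if (is.data.frame(delta_e_rev)) delta_e_rev <- delta_e_rev$delta_e_rev[1]
  predict_shift <- function(r) {
    p <- c(Cl = 1)
    p[sub_ion] <- r
    ghk_reversal(sol_in, sol_standard, p) -
      ghk_reversal(sol_in, sol_substituted, p)
  }
  # predict_shift is increasing in the ratio, from the zero-permeability
  # floor at r = 0
  f <- function(r) predict_shift(r) - delta_e_rev
  f0 <- f(0); fU <- f(upper)
  if (f0 >= 0 && f0 <= boundary_tol) {
    # at (or, within measurement error, just past) the non-permeant floor
    ratio <- 0
  } else if (f0 > 0) {
    stop("observed shift ", signif(delta_e_rev, 4),
         " mV is more negative than the zero-permeability prediction (",
         signif(predict_shift(0), 4), " mV): no GHK solution",
         call. = FALSE)
  } else if (fU < 0) {
    stop("observed shift exceeds the prediction at ratio ", upper,
         " (", signif(predict_shift(upper), 4), " mV): no GHK solution ",
         "in bounds", call. = FALSE)
  } else {
    ratio <- stats::uniroot(f, c(0, upper), tol = 1e-9)$root
  }
  pred <- predict_shift(ratio)
  tibble::tibble(ratio = ratio, observed_shift = delta_e_rev,
                 predicted_shift = pred, residual = delta_e_rev - pred)
}
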
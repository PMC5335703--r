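# Physical constants (SI)
.const <- list(
  R = 8.31446261815324,   # J mol^-1 K^-1
  F = 96485.33212331,     # C mol^-1
  h = 6.62607015e-34,     # J s
  c = 2.99792458e8        # m s^-1
)

#' Default recording temperature
#'
#' Room temperature (25 degrees C) in kelvin, the temperature at which
#' whole-cell patch-clamp recordings are assumed to be performed.
#' @export
ACR_TEMPERATURE_K <- 298.15

#' RT/F in millivolts
#'
#' @param temperature Temperature in kelvin.
#' @return RT/F in mV.
#' @export
rt_over_f <- function(temperature = ACR_TEMPERATURE_K) {
  1000 * .const$R * temperature / .const$F
}

#' Table of ionic species used in junction-potential and GHK computations
#'
#' Valences and aqueous mobilities of the ions appearing in the packaged
#' pipette and bath solutions.  Mobilities are expressed relative to K+
#' (u/u_K; the Henderson equation is invariant to this scale) and are taken
#' from the standard liquid-junction-potential tables used by patch-clamp
#' LJP calculators (Barry & Lynch 1991, J Membr Biol 121:101; Ng & Barry
#' 1995, J Neurosci Methods 56:37): K+ 1.000, Na+ 0.682, Ca2+ 0.4048,
#' Mg2+ 0.361, Cl- 1.0388, gluconate- 0.33, aspartate- 0.30.  HEPES- and
#' EGTA2- mobilities are the approximate large-organic-anion values from
#' the same sources.  The `permeability` column holds the default relative
#' channel permeabilities used by the GHK helpers: chloride is the
#' reference anion (P = 1) and every other species defaults to 0, the
#' anion-selective limit; aspartate in particular is the standard
#' non-permeant substitution anion.
#'
#' @return A tibble with columns `ion`, `valence`, `mobility`
#'   (relative to K+), `permeability`.
#' @export
ion_table <- function() {
  tibble::tribble(
    ~ion,        ~valence, ~mobility, ~permeability,
    "K",          1L,       1.0000,    0,
    "Na",         1L,       0.6820,    0,
    "Ca",         2L,       0.4048,    0,
    "Mg",         2L,       0.3610,    0,
    "Cl",        -1L,       1.0388,    1,
    "Asp",       -1L,       0.3000,    0,
    "Gluconate", -1L,       0.3300,    0,
    "HEPES",     -1L,       0.3000,    0,
    "EGTA",      -2L,       0.2400,    0
  )
}

.ion_lookup <- function(ions, field) {
  tab <- ion_table()
  idx <- match(ions, tab$ion)
  if (anyNA(idx)) {
    stop("unknown ion(s): ", paste(ions[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  tab[[field]][idx]
}
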
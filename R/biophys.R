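#' Nernst equilibrium potential
#'
#' Equilibrium (reversal) potential of a single ionic species,
#' `(RT/zF) * ln(c_out/c_in)`, in mV.  For the packaged solutions the
#' chloride Nernst potential (131 mM in, 155.6 mM out) is -4.42 mV.
#'
#' @param valence Signed integer charge (nonzero).
#' @param c_in,c_out Intra-/extracellular concentrations, mM (both > 0).
#' @param temperature Temperature in kelvin.
#' @return Potential in mV.
#' @examples
#' nernst_potential(-1, 131, 155.6)
#' @export
nernst_potential <- function(valence, c_in, c_out,
                             temperature = ACR_TEMPERATURE_K) {
  if (any(valence == 0)) stop("valence must be nonzero", call. = FALSE)
  if (any(c_in <= 0) || any(c_out <= 0)) {
    stop("concentrations must be > 0 for a Nernst potential", call. = FALSE)
  }
  rt_over_f(temperature) / valence * log(c_out / c_in)
}

# u/(1 - e^-u), the GHK flux factor, stable through u = 0
.ghk_g <- function(u) {
  out <- ifelse(abs(u) < 1e-10, 1 + u / 2, u / (-expm1(-u)))
  out
}

#' Goldman-Hodgkin-Katz current for one ionic species
#'
#' Constant-field current density
#' `I = P z^2 (V F^2 / RT) (c_in - c_out e^{-zVF/RT}) / (1 - e^{-zVF/RT})`,
#' evaluated in a numerically stable form that is continuous at V = 0,
#' where it equals `P z F (c_in - c_out)`.  The scale is arbitrary
#' (per unit permeability, concentrations in mM); only ratios, signs and
#' zero crossings are meaningful.
#'
#' @param v Membrane potential, mV (vectorised).
#' @param valence Signed integer charge.
#' @param c_in,c_out Concentrations, mM (>= 0).
#' @param permeability Relative permeability (>= 0).
#' @param temperature Temperature in kelvin.
#' @return Signed current (arbitrary units); positive = outward.
#' @export
ghk_current <- function(v, valence, c_in, c_out, permeability = 1,
                        temperature = ACR_TEMPERATURE_K) {
  if (any(c_in < 0) || any(c_out < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (any(permeability < 0)) stop("permeability must be >= 0", call. = FALSE)
  if (any(valence == 0)) stop("valence must be nonzero", call. = FALSE)
  u <- valence * v / rt_over_f(temperature)
  permeability * valence * .const$F / 1e6 *
    (c_in * .ghk_g(u) - c_out * .ghk_g(-u))
}

#' GHK reversal potential of a multi-ion conductance
#'
#' Zero-current voltage of the summed single-ion GHK currents, found by
#' numeric root bracketing (valid for any mix of valences, including
#' divalents).  With a single permeant ion this reduces to the Nernst
#' potential.
#'
#' @param sol_in,sol_out Intra-/extracellular [solution()] objects.
#' @param permeabilities Named vector of relative permeabilities; defaults
#'   to the [ion_table()] column (chloride-selective: `Cl = 1`, all other
#'   species 0).  Ions absent from the vector get permeability 0.
#' @param bracket Voltage search interval, mV.
#' @return Reversal potential in mV.
#' @examples
#' ghk_reversal(pipette_solution(), standard_bath())  # Cl Nernst, -4.42 mV
#' @export
ghk_reversal <- function(sol_in, sol_out, permeabilities = NULL,
                         bracket = c(-500, 500)) {
  stopifnot(inherits(sol_in, "acr_solution"), inherits(sol_out, "acr_solution"))
  ions <- union(names(sol_in$ions), names(sol_out$ions))
  perm <- stats::setNames(.ion_lookup(ions, "permeability"), ions)
  if (!is.null(permeabilities)) {
    # ions named in the permeability set but absent from both solutions
    # simply contribute no flux
    perm[] <- 0
    known <- intersect(names(permeabilities), ions)
    perm[known] <- permeabilities[known]
  }
  cin <- stats::setNames(rep(0, length(ions)), ions)
  cout <- cin
  cin[names(sol_in$ions)] <- sol_in$ions
  cout[names(sol_out$ions)] <- sol_out$ions
  active <- perm > 0 & (cin > 0 | cout > 0)
  if (!any(active)) {
    stop("no conductance: every ion has zero permeability or zero ",
         "concentration on both sides", call. = FALSE)
  }
  z <- .ion_lookup(ions, "valence")
  temperature <- sol_in$temperature
  total <- function(v) {
    sum(ghk_current(v, z[active], cin[active], cout[active],
                    perm[active], temperature))
  }
  lo <- total(bracket[1]); hi <- total(bracket[2])
  if (sign(lo) == sign(hi)) {
    stop("GHK current does not change sign in [", bracket[1], ", ",
         bracket[2], "] mV", call. = FALSE)
  }
  stats::uniroot(total, bracket, tol = 1e-10)$root
}

#' Henderson liquid-junction potential
#'
#' Junction potential between two solutions by the Henderson equation,
#' the same approximation used by patch-clamp LJP calculators:
#' \deqn{E = \frac{RT}{F}\,
#'   \frac{\sum_i (z_i u_i/|z_i|)(c_i^B - c_i^A)}
#'        {\sum_i z_i^2 u_i (c_i^B - c_i^A)}
#'   \ln\frac{\sum_i z_i^2 u_i c_i^A}{\sum_i z_i^2 u_i c_i^B}}
#' Sign convention: the returned value is the potential of solution B
#' minus solution A at the junction.  To correct patch-clamp data,
#' compute the LJP with A = pipette and B = bath and subtract it from the
#' command voltage (see [build_iv()]).
#'
#' @param sol_a,sol_b [solution()] objects (A and B).
#' @param mobilities Optional named vector overriding the packaged
#'   relative mobilities in [ion_table()].
#' @return Junction potential in mV; exactly 0 for identical solutions.
#' @examples
#' henderson_ljp(pipette_solution(), standard_bath())
#' @export
henderson_ljp <- function(sol_a, sol_b, mobilities = NULL) {
  stopifnot(inherits(sol_a, "acr_solution"), inherits(sol_b, "acr_solution"))
  ions <- union(names(sol_a$ions), names(sol_b$ions))
  ca <- stats::setNames(rep(0, length(ions)), ions)
  cb <- ca
  ca[names(sol_a$ions)] <- sol_a$ions
  cb[names(sol_b$ions)] <- sol_b$ions
  if (isTRUE(all.equal(ca, cb, tolerance = 0))) return(0)
  if (all(ca == cb)) return(0)
  z <- .ion_lookup(ions, "valence")
  u <- .ion_lookup(ions, "mobility")
  if (!is.null(mobilities)) {
    known <- intersect(names(mobilities), ions)
    u[match(known, ions)] <- mobilities[known]
  }
  if (any(is.na(u) | u <= 0)) stop("missing mobility", call. = FALSE)
  d <- cb - ca
  s1 <- sum(z * u / abs(z) * d)
  s2 <- sum(z^2 * u * d)
  ga <- sum(z^2 * u * ca)
  gb <- sum(z^2 * u * cb)
  if (s2 == 0 || ga <= 0 || gb <= 0) {
    stop("Henderson equation degenerate for these solutions", call. = FALSE)
  }
  rt_over_f(sol_a$temperature) * (s1 / s2) * log(ga / gb)
}

#' Photon flux density from optical power
#'
#' Converts an irradiance to a photon (quantum) flux density,
#' `flux = power * lambda / (h c)`.  At the calibration point of the
#' recording setup (7.6 mW/mm^2 at 520 nm) this is 1.99e16
#' photons mm^-2 s^-1.
#'
#' @param power Irradiance in mW/mm^2 (>= 0, vectorised).
#' @param lambda Wavelength in nm (> 0).
#' @return Photon flux density in photons mm^-2 s^-1.
#' @export
photon_flux_density <- function(power, lambda) {
  if (any(power < 0)) stop("power must be >= 0", call. = FALSE)
  if (any(lambda <= 0)) stop("wavelength must be > 0", call. = FALSE)
  (power * 1e-3) * (lambda * 1e-9) / (.const$h * .const$c)
}
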
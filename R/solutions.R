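#' Construct an ionic solution
#'
#' A solution is a named vector of free ionic concentrations (mM) plus pH
#' and temperature.  Only species listed in [ion_table()] may appear.
#' Neutral components (glucose, protonated HEPES) are omitted: HEPES is
#' zwitterionic near pH 7.4 and is treated as uncharged throughout.
#'
#' @param ... Named concentrations in mM, e.g. `Cl = 155.6, Na = 150`.
#' @param pH Solution pH (recorded, not currently used in computations).
#' @param temperature Temperature in kelvin.
#' @return An object of class `acr_solution`.
#' @examples
#' standard_bath()
#' solution(K = 126, Cl = 126)
#' @export
solution <- function(..., pH = 7.4, temperature = ACR_TEMPERATURE_K) {
  ions <- c(...)
  if (length(ions) == 0) stop("a solution needs at least one ion", call. = FALSE)
  if (is.null(names(ions)) || any(names(ions) == "")) {
    stop("all concentrations must be named by ion", call. = FALSE)
  }
  if (any(ions < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
  .ion_lookup(names(ions), "valence")  # validates ion names
  structure(
    list(ions = ions, pH = pH, temperature = temperature),
    class = "acr_solution"
  )
}

#' @export
print.acr_solution <- function(x, ...) {
  cat("<acr_solution> pH", x$pH, " T =", x$temperature, "K\n")
  print(tibble::tibble(ion = names(x$ions), mM = unname(x$ions)))
  invisible(x)
}

#' Packaged pipette solution
#'
#' Free-ion composition of the whole-cell pipette solution
#' (KCl 126, MgCl2 2, CaCl2 0.5, Na-EGTA 5, HEPES 25 mM, pH 7.4):
#' full salt dissociation gives 131 mM Cl-; Na-EGTA is taken as the
#' disodium salt (10 mM Na+, 5 mM EGTA2-); HEPES is treated as neutral.
#'
#' @return An `acr_solution`.
#' @export
pipette_solution <- function() {
  solution(K = 126, Na = 10, Mg = 2, Ca = 0.5, Cl = 131, EGTA = 5, pH = 7.4)
}

#' Packaged standard bath solution
#'
#' Free-ion composition of the standard bath
#' (NaCl 150, CaCl2 1.8, MgCl2 1, glucose 5, HEPES 10 mM, pH 7.4):
#' 155.6 mM Cl- on full dissociation; glucose and HEPES neutral.
#'
#' @return An `acr_solution`.
#' @export
standard_bath <- function() {
  solution(Na = 150, Ca = 1.8, Mg = 1, Cl = 155.6, pH = 7.4)
}

#' Aspartate-substituted bath
#'
#' Bath in which a fraction of the NaCl is replaced mole-for-mole by
#' sodium aspartate, the standard non-permeant anion substitution used to
#' shift the chloride reversal potential.  The published protocol states
#' only "partial replacement"; 70% is the packaged default.
#'
#' @param fraction Fraction of the 150 mM NaCl replaced by Na-aspartate.
#' @return An `acr_solution` with `Cl = 155.6 - 150*fraction` and
#'   `Asp = 150*fraction` (divalent salts untouched).
#' @export
aspartate_bath <- function(fraction = 0.7) {
  stopifnot(fraction >= 0, fraction <= 1)
  solution(Na = 150, Ca = 1.8, Mg = 1,
           Cl = 155.6 - 150 * fraction, Asp = 150 * fraction, pH = 7.4)
}

#' Read / write solutions as YAML
#'
#' Solutions are serialised as a mapping with keys `ions` (ion -> mM),
#' `pH` and `temperature`; a file may hold one solution or a named map of
#' several.
#'
#' @param path File path.
#' @return `read_solutions()`: a named list of `acr_solution`;
#'   `write_solutions()`: `path`, invisibly.
#' @export
read_solutions <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$ions)) raw <- list(solution = raw)
  purrr::map(raw, function(s) {
    do.call(solution, c(as.list(unlist(s$ions)),
                        list(pH = s$pH %||% 7.4,
                             temperature = s$temperature %||% ACR_TEMPERATURE_K)))
  })
}

#' @rdname read_solutions
#' @param solutions Named list of `acr_solution` objects.
#' @export
write_solutions <- function(solutions, path) {
  stopifnot(is.list(solutions), !is.null(names(solutions)))
  out <- purrr::map(solutions, function(s) {
    list(ions = as.list(s$ions), pH = s$pH, temperature = s$temperature)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
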
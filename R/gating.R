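#' Kinetic parameters of the three-state gating model
#'
#' Minimal closed/open/desensitized (C/O/D) scheme that reproduces the
#' peak-stationary-decay phenomenology of ACR photocurrents under a
#' rectangular light pulse: during light C -> O at
#' `k_act = k_act_max * template(lambda) * I/(I + I50)`, O -> D at `k_d`
#' and D -> O at `k_r`; after light-off O -> C at `k_close` (= 1/tau_off)
#' and D -> C at `k_rec`.  With saturating light the stationary open
#' fraction is `k_r/(k_d + k_r)`, so `(k_d, k_r)` set the percent
#' inactivation; `k_close` sets the mono-exponential off-decay.
#'
#' @param k_act_max Saturating activation rate, s^-1.
#' @param I50 Half-saturating intensity, mW/mm^2 (defined at
#'   `lambda_max`).
#' @param k_d,k_r Open->desensitized and desensitized->open rates, s^-1.
#' @param k_close Open->closed rate after light-off, s^-1 (> 0).
#' @param k_rec Desensitized->closed rate after light-off, s^-1;
#'   defaults to `k_close`, which makes the off-decay of the open state
#'   exactly single-exponential.
#' @param lambda_max Spectral maximum, nm.
#' @param g_scale Slope conductance at the reversal potential, nS.
#' @param permeabilities Named relative permeabilities (reference Cl = 1).
#' @return An object of class `acr_kinetics`.
#' @examples
#' kinetic_params(k_d = 0.25, k_r = 1.75)        # 12.5% inactivation
#' kinetic_params(tau_off_ms = 2.3)              # ZipACR-like closing
#' @param tau_off_ms Convenience alternative to `k_close`: off-decay
#'   time constant in ms.
#' @export
kinetic_params <- function(k_act_max = 500, I50 = 1,
                           k_d = 0.25, k_r = 1.75,
                           k_close = NULL, tau_off_ms = 2.3,
                           k_rec = NULL,
                           lambda_max = 515, g_scale = 10,
                           permeabilities = c(Cl = 1)) {
  k_close <- k_close %||% (1000 / tau_off_ms)
  k_rec <- k_rec %||% k_close
  rates <- c(k_act_max = k_act_max, I50 = I50, k_d = k_d, k_r = k_r,
             k_close = k_close, k_rec = k_rec)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (k_close <= 0) stop("k_close must be > 0", call. = FALSE)
  if (g_scale < 0) stop("g_scale must be >= 0", call. = FALSE)
  structure(
    list(k_act_max = k_act_max, I50 = I50, k_d = k_d, k_r = k_r,
         k_close = k_close, k_rec = k_rec, lambda_max = lambda_max,
         g_scale = g_scale, permeabilities = permeabilities),
    class = "acr_kinetics"
  )
}

#' Light stimulation protocol
#'
#' @param wavelength Monochromatic stimulus wavelength, nm.
#' @param intensity Irradiance, mW/mm^2 (>= 0).
#' @param on_time,off_time Light epoch, ms (`off_time > on_time`).
#' @param half_bandwidth Monochromator half-bandwidth, nm (annotation).
#' @return An object of class `acr_light`.
#' @export
light_protocol <- function(wavelength = 515, intensity = 7.6,
                           on_time = 50, off_time = 1050,
                           half_bandwidth = 10) {
  if (off_time <= on_time) stop("off_time must exceed on_time", call. = FALSE)
  if (intensity < 0) stop("intensity must be >= 0", call. = FALSE)
  structure(list(wavelength = wavelength, intensity = intensity,
                 on_time = on_time, off_time = off_time,
                 half_bandwidth = half_bandwidth),
            class = "acr_light")
}

#' Recording (acquisition) configuration
#'
#' Emulates the patch-clamp acquisition chain: sampling at
#' `sampling_rate` (default 5 kHz), a 4-pole low-pass filter
#' approximating the 2-kHz Bessel anti-alias filter, and additive
#' Gaussian noise whose post-filter RMS equals `noise_sd`.
#'
#' @param sampling_rate Hz (> 2 * `filter_cutoff`).
#' @param filter_cutoff Hz; `NA` disables filtering.
#' @param noise_sd Target output noise RMS, pA (>= 0).
#' @param seed Integer RNG seed; `NA` leaves the RNG stream untouched.
#' @return An object of class `acr_recording`.
#' @export
recording_config <- function(sampling_rate = 5000, filter_cutoff = 2000,
                             noise_sd = 0, seed = NA_integer_) {
  if (!is.na(filter_cutoff) && sampling_rate <= 2 * filter_cutoff) {
    stop("sampling_rate must exceed 2 * filter_cutoff", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(sampling_rate = sampling_rate,
                 filter_cutoff = filter_cutoff,
                 noise_sd = noise_sd, seed = seed),
            class = "acr_recording")
}

#' Integrate the three-state gating model
#'
#' Fixed-step 4th-order Runge-Kutta integration of the C/O/D occupancies
#' under a rectangular light pulse.  Occupancies start at C = 1 and sum
#' to 1 throughout.
#'
#' @param params [kinetic_params()].
#' @param light [light_protocol()].
#' @param dt Integration step, ms (default 0.02; must satisfy
#'   `dt * max(rate) < 0.5` for stability).
#' @param t_end End of integration, ms; default runs 8 off-decay time
#'   constants (at least 20 ms) past light-off.
#' @return A tibble of class `acr_gating` with columns `time`, `C`, `O`,
#'   `D`, carrying `light`, `params` and `dt` as attributes.
#' @export
simulate_gating <- function(params, light = light_protocol(), dt = 0.02,
                            t_end = NULL) {
  stopifnot(inherits(params, "acr_kinetics"), inherits(light, "acr_light"))
  k_act <- params$k_act_max *
    pigment_template(light$wavelength, params$lambda_max) *
    light$intensity / (light$intensity + params$I50) / 1000  # ms^-1
  k_d <- params$k_d / 1000
  k_r <- params$k_r / 1000
  k_close <- params$k_close / 1000
  k_rec <- params$k_rec / 1000
  if (dt * max(k_act, k_d, k_r, k_close, k_rec) > 0.5) {
    stop("dt too large for these rates: reduce dt for a stable ",
         "integration", call. = FALSE)
  }
  t_end <- t_end %||% (light$off_time + max(20, 8 / k_close))
  times <- seq(0, t_end, by = dt)
  n <- length(times)
  O <- D <- numeric(n)
  # piecewise-linear system in (O, D); C = 1 - O - D
  deriv_on <- function(s) {
    c(k_act * (1 - s[1] - s[2]) - k_d * s[1] + k_r * s[2],
      k_d * s[1] - k_r * s[2])
  }
  deriv_off <- function(s) c(-k_close * s[1], -k_rec * s[2])
  s <- c(0, 0)
  for (i in seq_len(n - 1)) {
    lit <- times[i] >= light$on_time && times[i] < light$off_time
    f <- if (lit) deriv_on else deriv_off
    k1 <- f(s)
    k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    O[i + 1] <- s[1]; D[i + 1] <- s[2]
  }
  out <- tibble::tibble(time = times, C = 1 - O - D, O = O, D = D)
  structure(out, class = c("acr_gating", class(out)),
            light = light, params = params, dt = dt)
}

# summed GHK current of the permeant ions at corrected voltage v,
# normalised so that the slope at the reversal potential is 1
# (units: mV of driving force; g_scale in nS then yields pA)
.ghk_driving <- function(v, sol_in, sol_out, permeabilities) {
  ions <- names(permeabilities)[permeabilities > 0]
  cin <- sol_in$ions[ions]; cin[is.na(cin)] <- 0
  cout <- sol_out$ions[ions]; cout[is.na(cout)] <- 0
  z <- .ion_lookup(ions, "valence")
  total <- function(vv) {
    vapply(vv, function(v1) {
      sum(ghk_current(v1, z, cin, cout, permeabilities[ions],
                      sol_in$temperature))
    }, numeric(1))
  }
  er <- ghk_reversal(sol_in, sol_out, permeabilities)
  slope <- (total(er + 0.5) - total(er - 0.5))  # per mV
  total(v) / slope
}

#' Synthesize a photocurrent trace from a gating time course
#'
#' `I(t) = g_scale * O(t) * u(V)` where `u(V)` is the summed GHK current
#' of the permeant ions at the LJP-corrected voltage, normalised to unit
#' slope at the reversal potential (so `g_scale` is the slope conductance
#' there, in nS, and currents come out in pA).  The trace is resampled to
#' the acquisition rate, noise is added, and the acquisition filter is
#' applied; the command voltage and the Henderson LJP are stored as
#' annotations.
#'
#' @param gating Output of [simulate_gating()].
#' @param v_command Command holding voltage, mV (amplifier output,
#'   uncorrected).
#' @param sol_in,sol_out Pipette and bath [solution()]s.
#' @param rec [recording_config()].
#' @return An [acr_trace()] in pA.
#' @export
synthesize_trace <- function(gating, v_command,
                             sol_in = pipette_solution(),
                             sol_out = standard_bath(),
                             rec = recording_config()) {
  stopifnot(inherits(gating, "acr_gating"), inherits(rec, "acr_recording"))
  params <- attr(gating, "params")
  light <- attr(gating, "light")
  ljp <- henderson_ljp(sol_in, sol_out)
  v_corr <- v_command - ljp
  drive <- .ghk_driving(v_corr, sol_in, sol_out, params$permeabilities)
  ts <- seq(0, max(gating$time), by = 1000 / rec$sampling_rate)
  o <- stats::approx(gating$time, gating$O, xout = ts)$y
  signal <- params$g_scale * o * drive
  value <- .acquire(signal, rec)
  acr_trace(ts, value, unit = "pA",
            light_on = light$on_time, light_off = light$off_time,
            v_command = v_command, ljp = ljp,
            sampling_rate = rec$sampling_rate, seed = rec$seed)
}

# acquisition chain: add white noise scaled so that the *filtered* noise
# RMS equals noise_sd, then low-pass filter signal + noise
.acquire <- function(signal, rec) {
  n <- length(signal)
  use_filter <- !is.na(rec$filter_cutoff)
  if (use_filter) {
    bf <- signal::butter(4, 2 * rec$filter_cutoff / rec$sampling_rate,
                         type = "low")
    h2 <- sum(signal::filter(bf, c(1, rep(0, 1023)))^2)
  } else {
    h2 <- 1
  }
  noise <- if (rec$noise_sd > 0) {
    if (!is.na(rec$seed)) {
      rng <- .seeded_rng(rec$seed)
      on.exit(rng(), add = TRUE)
    }
    stats::rnorm(n, 0, rec$noise_sd / sqrt(h2))
  } else {
    numeric(n)
  }
  x <- signal + noise
  if (use_filter) x <- as.numeric(signal::filter(bf, x))
  x
}

# set the RNG seed, returning a restorer for the previous state
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Synthesize a current-voltage family of photocurrent traces
#'
#' One trace per holding voltage and bath condition, sharing a single
#' gating time course (gating is voltage-independent in this model).
#' The default voltage grid is the 20-mV-step protocol from -60 to
#' +60 mV.  A warning flag is raised when the grid does not bracket the
#' reversal potential of a condition.
#'
#' @param params [kinetic_params()].
#' @param voltages Command voltages, mV (>= 2, should span the reversal).
#' @param conditions Named list of bath [solution()]s; default standard
#'   and 70% aspartate-substituted baths.
#' @param pipette Pipette [solution()].
#' @param light [light_protocol()].
#' @param rec [recording_config()]; seeds are offset per trace so that
#'   noise differs across traces but the family is reproducible.
#' @return A tibble of class `acr_iv_family` with columns `condition`,
#'   `v_command`, `ljp`, `trace` (list of [acr_trace()]), and attribute
#'   `bracket_warning`.
#' @export
synthesize_iv_family <- function(params,
                                 voltages = seq(-60, 60, by = 20),
                                 conditions = list(
                                   standard = standard_bath(),
                                   substituted = aspartate_bath()
                                 ),
                                 pipette = pipette_solution(),
                                 light = light_protocol(),
                                 rec = recording_config()) {
  if (length(voltages) < 2) stop("need >= 2 voltages", call. = FALSE)
  if (anyDuplicated(voltages)) stop("duplicate voltages", call. = FALSE)
  gating <- simulate_gating(params, light)
  warn <- FALSE
  rows <- purrr::imap(conditions, function(bath, cond) {
    ljp <- henderson_ljp(pipette, bath)
    er <- ghk_reversal(pipette, bath, params$permeabilities)
    vc <- sort(voltages) - ljp
    if (er < min(vc) || er > max(vc)) warn <<- TRUE
    traces <- purrr::imap(sort(voltages), function(v, i) {
      rec_i <- rec
      if (!is.na(rec$seed)) {
        rec_i$seed <- rec$seed + 1000L * match(cond, names(conditions)) + i
      }
      synthesize_trace(gating, v, pipette, bath, rec_i)
    })
    tibble::tibble(condition = cond, v_command = sort(voltages),
                   ljp = ljp, trace = traces)
  })
  out <- dplyr::bind_rows(rows)
  if (warn) {
    warning("voltage grid does not bracket the reversal potential of at ",
            "least one condition", call. = FALSE)
  }
  structure(out, class = c("acr_iv_family", class(out)),
            bracket_warning = warn, params = params)
}

#' Synthesize low-intensity spectral-scan responses
#'
#' Emulates the action-spectrum protocol: initial-slope photocurrent
#' responses to weak monochromatic pulses, scanned from the shortest to
#' the longest wavelength and back again.  In the linear range the
#' response is proportional to `template(lambda) * photon_flux(lambda)`;
#' multiplicative Gaussian noise and an optional linear sensitivity
#' drift (fractional change per scan step, emulating rundown) are
#' applied.  Averaging the two scan directions cancels such a drift to
#' first order.
#'
#' @param params [kinetic_params()] (supplies `lambda_max`).
#' @param wavelengths Scanned wavelengths, nm.
#' @param power Irradiance used at every wavelength, mW/mm^2; should be
#'   well below `I50` (a warning flag is raised otherwise).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param drift Fractional sensitivity change per scan step (default 0).
#' @param seed RNG seed (`NA` = leave stream untouched).
#' @param scale Response scale factor, pA per unit template x flux.
#' @return A tibble of class `acr_spectral_scan` with columns
#'   `wavelength`, `direction` ("forward"/"reverse"), `order`, `power`,
#'   `response`; attributes `lambda_max_true`, `linear_range_warning`.
#' @export
synthesize_spectral_responses <- function(params,
                                          wavelengths = seq(400, 600, 10),
                                          power = 0.02,
                                          noise_cv = 0, drift = 0,
                                          seed = NA_integer_,
                                          scale = 1e-14) {
  stopifnot(inherits(params, "acr_kinetics"))
  nonlinear <- power > 0.1 * params$I50
  if (nonlinear) {
    warning("intensity beyond the linear range (power > 0.1 * I50)",
            call. = FALSE)
  }
  wl <- sort(wavelengths)
  protocol <- tibble::tibble(
    wavelength = c(wl, rev(wl)),
    direction = rep(c("forward", "reverse"), each = length(wl)),
    order = seq_len(2 * length(wl)),
    power = power
  )
  base <- pigment_template(protocol$wavelength, params$lambda_max) *
    photon_flux_density(power, protocol$wavelength) * scale
  sens <- 1 + drift * (protocol$order - mean(protocol$order))
  if (!is.na(seed)) {
    restore <- .seeded_rng(seed)
    on.exit(restore(), add = TRUE)
  }
  mult <- if (noise_cv > 0) {
    pmax(stats::rnorm(nrow(protocol), 1, noise_cv), 0.01)
  } else 1
  protocol$response <- base * sens * mult
  structure(protocol, class = c("acr_spectral_scan", class(protocol)),
            lambda_max_true = params$lambda_max,
            linear_range_warning = nonlinear, seed = seed)
}
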
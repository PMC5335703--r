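#' Leaky integrate-and-fire neuron parameters
#'
#' Packaged defaults describe a hippocampal-pyramidal-like cell
#' (membrane time constant 10 ms) for which the default 2.5-nA, 1-ms
#' stimulus pulse fires exactly one spike per pulse in the dark.
#'
#' @param capacitance Membrane capacitance, pF (> 0).
#' @param leak_conductance Leak conductance, nS (> 0).
#' @param v_rest,v_thresh,v_reset Resting, threshold and reset
#'   potentials, mV (`v_thresh > v_reset`).
#' @param refractory Absolute refractory period, ms.
#' @return An object of class `acr_lif`.
#' @export
lif_params <- function(capacitance = 100, leak_conductance = 10,
                       v_rest = -70, v_thresh = -50, v_reset = -65,
                       refractory = 2) {
  if (capacitance <= 0 || leak_conductance <= 0) {
    stop("capacitance and leak must be > 0", call. = FALSE)
  }
  if (v_thresh <= v_reset) stop("v_thresh must exceed v_reset", call. = FALSE)
  structure(list(capacitance = capacitance,
                 leak_conductance = leak_conductance,
                 v_rest = v_rest, v_thresh = v_thresh, v_reset = v_reset,
                 refractory = refractory),
            class = "acr_lif")
}

#' 50-Hz style somatic current-pulse train
#'
#' @param n Number of pulses.
#' @param start First pulse onset, ms.
#' @param interval Inter-pulse interval, ms (20 ms = 50 Hz).
#' @param amplitude Pulse amplitude, pA.
#' @param width Pulse width, ms.
#' @return An object of class `acr_stim`.
#' @export
stim_train <- function(n = 20, start = 10, interval = 20,
                       amplitude = 2500, width = 1) {
  structure(list(times = start + interval * (seq_len(n) - 1),
                 amplitude = amplitude, width = width,
                 interval = interval),
            class = "acr_stim")
}

# peak depolarisation of one pulse from rest, leak only (closed form)
.lif_pulse_peak <- function(lif, stim) {
  tau <- lif$capacitance / lif$leak_conductance
  lif$v_rest + stim$amplitude / lif$leak_conductance *
    (1 - exp(-stim$width / tau))
}

#' Simulate optogenetic spike suppression in a LIF neuron
#'
#' Exponential-Euler integration of a leaky integrate-and-fire neuron
#' driven by a suprathreshold current-pulse train, with a light-gated
#' chloride conductance: the conductance steps to `g0` instantaneously at
#' light onset (channel opening is much faster than 1 ms) and decays
#' exponentially with `tau_off` after light-off.  Spikes are threshold
#' crossings followed by reset and an absolute refractory period; at a
#' spike the stored voltage is set to +20 mV for one sample so that
#' spikes are visible in the trace.
#'
#' With `g0 = 0` (or `light_windows = NULL`) the simulation is the dark
#' control and fires one spike per stimulus pulse by construction; a
#' subthreshold dark stimulus is a configuration error.
#'
#' @param lif [lif_params()].
#' @param stim [stim_train()].
#' @param g0 Light-gated conductance amplitude, nS.
#' @param e_rev Reversal potential of the light-gated conductance, mV.
#' @param tau_off Off-decay time constant of the conductance, ms.
#' @param light_windows Matrix-like list of `c(on, off)` pairs in ms, or
#'   a single `c(on, off)`; `NULL` for the dark control.
#' @param t_end Simulation end, ms; default covers the stimulus train.
#' @param dt Integration step, ms (default 0.01).
#' @return An [acr_trace()] in mV with `stim_times` annotation and a
#'   `spike_times` attribute.
#' @export
simulate_neuron_inhibition <- function(lif = lif_params(),
                                       stim = stim_train(),
                                       g0 = 200, e_rev = -75,
                                       tau_off = 2.3,
                                       light_windows = NULL,
                                       t_end = NULL, dt = 0.01) {
  stopifnot(inherits(lif, "acr_lif"), inherits(stim, "acr_stim"))
  if (.lif_pulse_peak(lif, stim) < lif$v_thresh) {
    stop("configuration error: stimulus pulses are subthreshold in the ",
         "dark (peak ", signif(.lif_pulse_peak(lif, stim), 4),
         " mV < threshold)", call. = FALSE)
  }
  if (is.numeric(light_windows) && is.null(dim(light_windows))) {
    light_windows <- list(light_windows)
  }
  t_end <- t_end %||% (max(stim$times) + stim$interval)
  stim$times <- stim$times[stim$times < t_end]
  if (length(stim$times) == 0) stop("no stimulus inside t_end", call. = FALSE)
  times <- seq(0, t_end, by = dt)
  n <- length(times)
  v <- numeric(n)
  v[1] <- lif$v_rest
  # precompute drive vectors
  i_stim <- numeric(n)
  for (s in stim$times) {
    i_stim[times >= s & times < s + stim$width] <- stim$amplitude
  }
  g_acr <- numeric(n)
  if (!is.null(light_windows) && g0 > 0) {
    for (w in light_windows) {
      g_acr[times >= w[1] & times < w[2]] <- g0
      post <- times >= w[2]
      g_acr[post] <- pmax(g_acr[post], g0 * exp(-(times[post] - w[2]) / tau_off))
    }
  }
  spike_times <- numeric(0)
  refr_until <- -Inf
  vv <- lif$v_rest
  for (i in seq_len(n - 1)) {
    g_tot <- lif$leak_conductance + g_acr[i]
    v_inf <- (lif$leak_conductance * lif$v_rest + g_acr[i] * e_rev +
                i_stim[i]) / g_tot
    if (times[i] < refr_until) {
      vv <- lif$v_reset
    } else {
      vv <- v_inf + (vv - v_inf) * exp(-dt * g_tot / lif$capacitance)
      if (vv >= lif$v_thresh) {
        spike_times <- c(spike_times, times[i + 1])
        v[i + 1] <- 20  # drawn spike
        refr_until <- times[i + 1] + lif$refractory
        vv <- lif$v_reset
        next
      }
    }
    v[i + 1] <- vv
  }
  out <- acr_trace(times, v, unit = "mV",
                   light_on = if (!is.null(light_windows))
                     light_windows[[1]][1] else NA_real_,
                   light_off = if (!is.null(light_windows))
                     light_windows[[1]][2] else NA_real_,
                   sampling_rate = 1000 / dt, stim_times = stim$times)
  attr(out, "spike_times") <- spike_times
  attr(out, "light_windows") <- light_windows
  attr(out, "lif") <- lif
  out
}

#' Rheobase from a slow current ramp
#'
#' Injects a linear current ramp (default 0-1000 pA over 1 s) into the
#' LIF model in the dark and reports the injected current at the first
#' threshold crossing.  For a slow ramp this approaches the quasi-static
#' limit `g_leak * (v_thresh - v_rest)`.
#'
#' @param lif [lif_params()].
#' @param ramp_max Final ramp current, pA.
#' @param ramp_duration Ramp duration, ms.
#' @param dt Integration step, ms.
#' @return Rheobase in pA, or `NA_real_` (the "no spike" sentinel) when
#'   the ramp never reaches threshold.
#' @export
measure_rheobase <- function(lif = lif_params(), ramp_max = 1000,
                             ramp_duration = 1000, dt = 0.01) {
  stopifnot(inherits(lif, "acr_lif"))
  times <- seq(0, ramp_duration, by = dt)
  i_t <- ramp_max * times / ramp_duration
  vv <- lif$v_rest
  tau <- lif$capacitance / lif$leak_conductance
  for (i in seq_along(times)[-1]) {
    v_inf <- lif$v_rest + i_t[i - 1] / lif$leak_conductance
    vv <- v_inf + (vv - v_inf) * exp(-dt / tau)
    if (vv >= lif$v_thresh) return(i_t[i])
  }
  NA_real_
}
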
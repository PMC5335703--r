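#' Spike metrics of a photoinhibition experiment
#'
#' Compares a light-trial voltage trace against its dark control
#' (identical simulation without light).  Spikes are upward threshold
#' crossings; each stimulus pulse is scored as fired or suppressed, the
#' per-stimulus response amplitude is the peak depolarisation from rest
#' within the stimulus window, and amplitudes are normalized to the mean
#' amplitude of the last five spikes before light onset (fewer, with a
#' warning, when fewer are available).  The suppressed count is the
#' number of stimuli that fire in the control but not under light.
#'
#' @param trace Light-trial [acr_trace()] in mV (e.g. from
#'   [simulate_neuron_inhibition()]).
#' @param control Dark-control trace from the identical simulation
#'   without light.
#' @param stim_times Stimulus onsets, ms; default from the trace
#'   annotation.
#' @param light_windows List of `c(on, off)` pairs; default from the
#'   trace annotation.
#' @param v_thresh Spike detection threshold, mV.
#' @param v_rest Resting potential used as the amplitude baseline, mV.
#' @return An object of class `acr_spike_metrics`: list with
#'   `per_stimulus` (tibble: `stim_time`, `fired_control`,
#'   `fired_light`, `amplitude`, `norm_amplitude`, `suppressed`),
#'   `suppressed_count`, `spike_times`, `baseline_n`.
#' @export
spike_analysis <- function(trace, control, stim_times = NULL,
                           light_windows = NULL,
                           v_thresh = -50, v_rest = -70) {
  stim_times <- stim_times %||% attr(trace, "stim_times")
  light_windows <- light_windows %||% attr(trace, "light_windows")
  if (is.null(stim_times)) stop("stimulus times required", call. = FALSE)
  stim_times <- stim_times[stim_times < max(trace$time)]
  lif <- attr(trace, "lif")
  if (!is.null(lif)) {
    v_thresh <- lif$v_thresh
    v_rest <- lif$v_rest
  }
  interval <- if (length(stim_times) > 1) min(diff(stim_times)) else
    max(trace$time) - stim_times
  score <- function(tr) {
    purrr::map_dfr(seq_along(stim_times), function(k) {
      s <- stim_times[k]
      win <- tr$time >= s & tr$time < s + interval
      seg <- tr$value[win]
      tibble::tibble(stim_index = k, stim_time = s,
                     fired = any(seg >= v_thresh),
                     amplitude = max(seg) - v_rest)
    })
  }
  light_tab <- score(trace)
  ctrl_tab <- score(control)
  first_on <- if (is.null(light_windows)) Inf else
    min(purrr::map_dbl(light_windows, 1))
  pre <- which(light_tab$stim_time < first_on & light_tab$fired)
  base_idx <- utils::tail(pre, 5)
  if (length(base_idx) < 5) {
    warning("fewer than 5 pre-light spikes; normalizing to ",
            length(base_idx), " spike(s)", call. = FALSE)
  }
  baseline <- mean(light_tab$amplitude[base_idx])
  per_stim <- light_tab |>
    dplyr::mutate(fired_control = ctrl_tab$fired,
                  fired_light = .data$fired,
                  norm_amplitude = .data$amplitude / baseline,
                  suppressed = .data$fired_control & !.data$fired_light) |>
    dplyr::select(dplyr::all_of(c(
      "stim_index", "stim_time", "fired_control", "fired_light",
      "amplitude", "norm_amplitude", "suppressed"
    )))
  structure(
    list(per_stimulus = per_stim,
         suppressed_count = sum(per_stim$suppressed),
         spike_times = attr(trace, "spike_times"),
         baseline_n = length(base_idx)),
    class = "acr_spike_metrics"
  )
}

#' @export
print.acr_spike_metrics <- function(x, ...) {
  cat("<acr_spike_metrics>", sum(x$per_stimulus$fired_light), "of",
      nrow(x$per_stimulus), "stimuli fired;", x$suppressed_count,
      "suppressed vs control\n")
  invisible(x)
}
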
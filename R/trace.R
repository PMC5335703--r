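#' Sampled recording trace
#'
#' The common container for synthetic and analysed recordings: a tibble
#' with columns `time` (ms) and `value` (pA for photocurrents, mV for
#' membrane voltage), uniformly sampled, carrying recording annotations
#' as attributes (`unit`, `light_on`/`light_off` in ms, `v_command`,
#' `ljp`, `sampling_rate` in Hz, `stim_times`, `seed`).
#'
#' @param time Sample times, ms (uniform spacing).
#' @param value Sample values.
#' @param unit `"pA"` or `"mV"`.
#' @param light_on,light_off Light epoch boundaries, ms (NA if unlit).
#' @param v_command Command (uncorrected) holding voltage, mV.
#' @param ljp Liquid-junction potential used for correction, mV.
#' @param sampling_rate Hz; inferred from `time` when NULL.
#' @param stim_times Stimulus (current-pulse) onset times, ms.
#' @param seed RNG seed used to generate the trace, if any.
#' @return A tibble of class `acr_trace`.
#' @export
acr_trace <- function(time, value, unit = "pA",
                      light_on = NA_real_, light_off = NA_real_,
                      v_command = NA_real_, ljp = 0,
                      sampling_rate = NULL, stim_times = NULL,
                      seed = NA_integer_) {
  stopifnot(length(time) == length(value), length(time) >= 2)
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop("trace must be uniformly sampled", call. = FALSE)
  }
  if (!is.na(light_on) && !is.na(light_off) && light_off <= light_on) {
    stop("light_off must exceed light_on", call. = FALSE)
  }
  out <- tibble::tibble(time = as.numeric(time), value = as.numeric(value))
  structure(out,
            class = c("acr_trace", class(out)),
            unit = unit, light_on = light_on, light_off = light_off,
            v_command = v_command, ljp = ljp,
            sampling_rate = sampling_rate %||% (1000 / stats::median(dt)),
            stim_times = stim_times, seed = seed)
}

#' @export
print.acr_trace <- function(x, ...) {
  cat("<acr_trace> ", nrow(x), " samples @ ",
      signif(attr(x, "sampling_rate"), 4), " Hz [", attr(x, "unit"), "]",
      sep = "")
  if (!is.na(attr(x, "light_on"))) {
    cat("  light ", attr(x, "light_on"), "-", attr(x, "light_off"), " ms",
        sep = "")
  }
  if (!is.na(attr(x, "v_command"))) {
    cat("  V_cmd ", attr(x, "v_command"), " mV (LJP ",
        signif(attr(x, "ljp"), 3), " mV)", sep = "")
  }
  cat("\n")
  NextMethod()
}

light_epoch <- function(trace) {
  ep <- c(attr(trace, "light_on"), attr(trace, "light_off"))
  if (anyNA(ep)) stop("trace has no annotated light epoch", call. = FALSE)
  ep
}

# linear interpolation of the trace value at arbitrary times
trace_value_at <- function(trace, t) {
  stats::approx(trace$time, trace$value, xout = t, rule = 2)$y
}

#' Write / read a trace as delimited text with a metadata sidecar
#'
#' The samples go to a two-column TSV (`time`, `value`); the annotations
#' go to `<path>.meta.yaml`.  `read_trace()` restores both.
#'
#' @param trace An [acr_trace()].
#' @param path TSV file path.
#' @return `write_trace()`: `path` invisibly; `read_trace()`: the trace.
#' @export
write_trace <- function(trace, path) {
  readr::write_tsv(tibble::as_tibble(trace), path)
  meta <- purrr::map(
    c("unit", "light_on", "light_off", "v_command", "ljp",
      "sampling_rate", "stim_times", "seed"),
    ~ attr(trace, .x)
  )
  names(meta) <- c("unit", "light_on", "light_off", "v_command", "ljp",
                   "sampling_rate", "stim_times", "seed")
  yaml::write_yaml(purrr::discard(meta, is.null), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  acr_trace(tab$time, tab$value,
            unit = meta$unit %||% "pA",
            light_on = meta$light_on %||% NA_real_,
            light_off = meta$light_off %||% NA_real_,
            v_command = meta$v_command %||% NA_real_,
            ljp = meta$ljp %||% 0,
            sampling_rate = meta$sampling_rate,
            stim_times = unlist(meta$stim_times),
            seed = meta$seed %||% NA_integer_)
}
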
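#' Single-exponential fit of the light-off current decay
#'
#' Least-squares fit of `I(t) = A exp(-(t - t0)/tau) + B` to the samples
#' after light-off.  Besides the time constant the fit reports the 90%-
#' and 50%-closing times `t90 = tau ln 10` and `t_half = tau ln 2`, the
#' quantities used to judge how fast a channel variant can track repeated
#' stimuli (a 2.3-ms time constant gives a 90% closing time of 5.3 ms,
#' i.e. single-spike resolution beyond 180 Hz).
#'
#' @param trace An [acr_trace()], or a data frame with `time`/`value`.
#' @param t0 Decay start (light-off), ms; defaults to the trace's
#'   annotated `light_off`.
#' @return An object of class `acr_decay_fit` with elements `tau` (ms),
#'   `amplitude`, `baseline`, `t90`, `t_half`, `sigma` (residual sd),
#'   `n`.  Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_exponential_decay <- function(trace, t0 = NULL) {
  t0 <- t0 %||% attr(trace, "light_off")
  if (is.null(t0) || is.na(t0)) stop("decay start t0 required", call. = FALSE)
  seg <- trace[trace$time >= t0, , drop = FALSE]
  if (nrow(seg) < 10) {
    stop("need at least 10 samples after t0 to fit a decay", call. = FALSE)
  }
  tt <- seg$time - t0
  y <- seg$value
  b0 <- mean(y[tt >= stats::quantile(tt, 0.9)])
  a0 <- y[1] - b0
  if (abs(a0) < 10 * .Machine$double.eps + 1e-3 * abs(b0) ||
      abs(a0) <= 1e-12) {
    stop("fit failure: segment is flat, no decaying component ",
         "(initial amplitude ", signif(a0, 3), ")", call. = FALSE)
  }
  # log-linear start for tau from the first two thirds of the segment
  early <- which(abs(y - b0) > 0.05 * abs(a0) & sign(y - b0) == sign(a0))
  if (length(early) < 3) {
    stop("fit failure: no resolvable decay above baseline", call. = FALSE)
  }
  if (abs(y[1]) <= abs(b0)) {
    stop("fit failure: segment does not decay (magnitude grows from ",
         signif(abs(y[1]), 3), " toward ", signif(abs(b0), 3), ")",
         call. = FALSE)
  }
  lf <- stats::lm(log(abs(y[early] - b0)) ~ tt[early])
  slope <- unname(stats::coef(lf)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("fit failure: segment does not decay (log-slope ",
         signif(slope, 3), " >= 0)", call. = FALSE)
  }
  tau0 <- -1 / slope
  # Levenberg-Marquardt is robust where plain Gauss-Newton hits a
  # singular gradient on (near-)zero-residual data
  fit <- try(minpack.lm::nlsLM(
    y ~ A * exp(-tt / tau) + B,
    start = list(A = a0, tau = tau0, B = b0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    co <- c(A = a0, tau = tau0, B = b0)
    sigma <- stats::sd(y - co["A"] * exp(-tt / co["tau"]) - co["B"])
  } else {
    co <- stats::coef(fit)
    sigma <- stats::sigma(fit)
  }
  structure(
    list(tau = unname(co["tau"]), amplitude = unname(co["A"]),
         baseline = unname(co["B"]),
         t90 = unname(co["tau"]) * log(10),
         t_half = unname(co["tau"]) * log(2),
         sigma = sigma, n = length(y), t0 = t0),
    class = "acr_decay_fit"
  )
}

#' @export
print.acr_decay_fit <- function(x, ...) {
  cat("<acr_decay_fit> tau =", signif(x$tau, 4), "ms  t1/2 =",
      signif(x$t_half, 4), "ms  t90 =", signif(x$t90, 4), "ms\n")
  invisible(x)
}

#' Half-decay time of the light-off current
#'
#' The model-free decay metric: the time after light-off at which the
#' current magnitude first falls to 50% of its value at the light-off
#' instant, located by linear interpolation between samples.  Its
#' reciprocal (in s^-1) is the decay rate used to summarise channel
#' closing speed across variants.
#'
#' @param trace An [acr_trace()] with an annotated light epoch.
#' @param reference `"light_off"` (default: 50% of the current at the
#'   light-off instant) or `"peak"` (50% of the in-light peak).
#' @return A one-row tibble with `t_half` (ms) and `rate` (s^-1).
#' @export
half_decay_time <- function(trace, reference = c("light_off", "peak")) {
  reference <- match.arg(reference)
  off <- light_epoch(trace)[2]
  i0 <- if (reference == "light_off") {
    trace_value_at(trace, off)
  } else {
    ep <- light_epoch(trace)
    seg <- trace$value[trace$time >= ep[1] & trace$time <= ep[2]]
    seg[which.max(abs(seg))]
  }
  if (abs(i0) == 0) stop("zero current at light-off", call. = FALSE)
  target <- abs(i0) / 2
  post <- trace[trace$time >= off, , drop = FALSE]
  mag <- abs(post$value)
  below <- which(mag <= target)
  if (length(below) == 0) {
    stop("censored: current never reaches 50% of its light-off value ",
         "within the record", call. = FALSE)
  }
  k <- below[1]
  if (k == 1) {
    t_half <- post$time[1] - off
  } else {
    # linear interpolation between the bracketing samples
    t1 <- post$time[k - 1]; t2 <- post$time[k]
    m1 <- mag[k - 1]; m2 <- mag[k]
    t_half <- t1 + (m1 - target) / (m1 - m2) * (t2 - t1) - off
  }
  t_half <- max(t_half, 0)
  tibble::tibble(t_half = t_half, rate = 1000 / t_half)
}
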
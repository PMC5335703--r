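# Independent oracles and fixture builders used across the suite.

# Exhaustive global-alignment score: enumerates every monotone alignment
# path, scoring matches by the substitution matrix and each gap run as
# open + len * extend (the same affine convention as global_align()).
# Exponential in sequence length; only for toy pairs.
align_score_exhaustive <- function(q, r, sm, open = 10, ext = 1) {
  qs <- strsplit(q, "")[[1]]
  rs <- strsplit(r, "")[[1]]
  nq <- length(qs); nr <- length(rs)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i > nq && j > nr) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= nq && j <= nr) {
      rec(i + 1, j + 1, "M", acc + sm[qs[i], rs[j]])
    }
    if (i <= nq) {
      rec(i + 1, j, "I", acc - (if (last == "I") ext else open + ext))
    }
    if (j <= nr) {
      rec(i, j + 1, "D", acc - (if (last == "D") ext else open + ext))
    }
  }
  rec(1L, 1L, "S", 0)
  best
}

# Trace with an exact single-exponential light-off decay, built directly
# (no gating model): plateau i0 during the light epoch, exponential tail.
make_decay_trace <- function(tau_ms, i0 = -500, light_on = 10,
                             light_off = 260, dt = 0.2,
                             tail_factor = 12) {
  t_end <- light_off + tail_factor * tau_ms
  times <- seq(0, t_end, by = dt)
  value <- ifelse(
    times < light_on, 0,
    ifelse(times <= light_off, i0,
           i0 * exp(-(times - light_off) / tau_ms))
  )
  acr_trace(times, value, light_on = light_on, light_off = light_off)
}

# random toy protein sequence
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
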
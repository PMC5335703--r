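test_that("gating occupancies are conserved and bounded", {
  g <- simulate_gating(kinetic_params(), light_protocol(off_time = 250),
                       t_end = 300)
  expect_true(all(abs(g$C + g$O + g$D - 1) < 1e-6))
  expect_true(all(g$O >= -1e-12 & g$O <= 1 + 1e-12))
  expect_true(all(g$D >= -1e-12 & g$D <= 1 + 1e-12))
})

test_that("stationary open fraction approaches k_r / (k_d + k_r)", {
  p <- kinetic_params(k_d = 1, k_r = 3)
  g <- simulate_gating(p, light_protocol(intensity = 1e6, on_time = 0,
                                         off_time = 4000),
                       dt = 0.05, t_end = 4000)
  expect_equal(g$O[nrow(g)], 3 / 4, tolerance = 1e-3)
})

test_that("zero desensitisation gives a non-inactivating open state", {
  p <- kinetic_params(k_d = 0, k_r = 0)
  g <- simulate_gating(p, light_protocol(intensity = 1e6))
  tr <- synthesize_trace(g, -60)
  expect_equal(max(g$O), 1, tolerance = 1e-3)
  expect_lt(inactivation_percent(tr), 0.5)
})

test_that("peak open fraction approaches 1 for fast activation", {
  p <- kinetic_params(k_act_max = 5e4, k_d = 5, k_r = 1)
  g <- simulate_gating(p, light_protocol(intensity = 1e6, on_time = 0,
                                         off_time = 25),
                       dt = 0.005, t_end = 30)
  expect_gt(max(g$O), 0.99)
})

test_that("light-off decay of O is single-exponential at rate k_close", {
  p <- kinetic_params(tau_off_ms = 2.3)  # k_rec defaults to k_close
  g <- simulate_gating(p, light_protocol(off_time = 250), t_end = 280)
  off <- attr(g, "light")$off_time
  post <- g[g$time >= off, ]
  o0 <- post$O[1]
  expect_equal(post$O, o0 * exp(-(post$time - off) / 2.3),
               tolerance = 1e-6)
})

test_that("an unstable integration step is refused", {
  expect_error(
    simulate_gating(kinetic_params(tau_off_ms = 0.01), light_protocol()),
    "dt"
  )
})

test_that("traces are reproducible bit-for-bit from the seed", {
  g <- simulate_gating(kinetic_params(), light_protocol(off_time = 250),
                       t_end = 300)
  rec <- recording_config(noise_sd = 5, seed = 42)
  t1 <- synthesize_trace(g, -60, rec = rec)
  t2 <- synthesize_trace(g, -60, rec = rec)
  expect_identical(t1$value, t2$value)
  t3 <- synthesize_trace(g, -60, rec = recording_config(noise_sd = 5,
                                                        seed = 43))
  expect_false(identical(t1$value, t3$value))
})

test_that("trace current is proportional to O(t) before noise", {
  g <- simulate_gating(kinetic_params(), light_protocol(off_time = 250),
                       t_end = 300)
  tr <- synthesize_trace(g, -60,
                         rec = recording_config(filter_cutoff = NA))
  o <- approx(g$time, g$O, xout = tr$time)$y
  scale <- tr$value[which.max(abs(tr$value))] / max(o)
  expect_equal(tr$value, scale * o, tolerance = 1e-6)
})

test_that("current vanishes at the reversal potential", {
  g <- simulate_gating(kinetic_params(), light_protocol(off_time = 250),
                       t_end = 300)
  er <- ghk_reversal(pipette_solution(), standard_bath())
  ljp <- henderson_ljp(pipette_solution(), standard_bath())
  tr <- synthesize_trace(g, er + ljp)
  expect_lt(max(abs(tr$value)), 1e-9)
})

test_that("filtered noise RMS matches the configured noise_sd", {
  g <- simulate_gating(kinetic_params(g_scale = 0),
                       light_protocol(off_time = 60), t_end = 100)
  rms <- vapply(1:40, function(s) {
    tr <- synthesize_trace(g, -60,
                           rec = recording_config(noise_sd = 10, seed = s))
    sqrt(mean(tr$value^2))
  }, numeric(1))
  expect_equal(mean(rms), 10, tolerance = 0.1)
})

test_that("the default IV family spans 7 voltages and both conditions", {
  fam <- synthesize_iv_family(kinetic_params())
  expect_equal(nrow(fam), 14)
  expect_setequal(unique(fam$condition), c("standard", "substituted"))
  expect_equal(sort(unique(fam$v_command)), seq(-60, 60, 20))
  # condition A and B differ only via the bath: same gating, same voltages
  expect_equal(fam$v_command[fam$condition == "standard"],
               fam$v_command[fam$condition == "substituted"])
})

test_that("a non-bracketing voltage grid raises the warning flag", {
  expect_warning(
    fam <- synthesize_iv_family(kinetic_params(), voltages = c(40, 60),
                                conditions = list(sub = aspartate_bath())),
    "bracket"
  )
  expect_true(attr(fam, "bracket_warning"))
})

test_that("noiseless IV zero-crossing matches the GHK reversal", {
  fam <- synthesize_iv_family(kinetic_params(),
                              conditions = list(standard = standard_bath()))
  er_est <- reversal_potential(build_iv(fam, "mean"))$e_rev
  er_true <- ghk_reversal(pipette_solution(), standard_bath())
  expect_lt(abs(er_est - er_true), 0.2)
})

test_that("spectral scans are symmetric without noise and flag nonlinearity", {
  p <- kinetic_params(lambda_max = 515)
  sc <- synthesize_spectral_responses(p, seq(450, 600, 25))
  fwd <- sc$response[sc$direction == "forward"]
  rev_ <- rev(sc$response[sc$direction == "reverse"])
  expect_equal(fwd, rev_)
  # response ratio at two wavelengths = template ratio x flux ratio
  r_gen <- sc$response[sc$wavelength == 500 & sc$direction == "forward"] /
    sc$response[sc$wavelength == 550 & sc$direction == "forward"]
  r_expect <- (pigment_template(500, 515) * photon_flux_density(0.02, 500)) /
    (pigment_template(550, 515) * photon_flux_density(0.02, 550))
  expect_equal(r_gen, r_expect, tolerance = 1e-12)
  expect_warning(
    synthesize_spectral_responses(p, seq(450, 600, 50), power = 5),
    "linear range"
  )
})

test_that("forward/reverse averaging cancels a linear sensitivity drift", {
  p <- kinetic_params(lambda_max = 515)
  drift <- synthesize_spectral_responses(p, seq(400, 600, 10), drift = 0.01)
  # single-direction estimate is biased, the averaged one is not
  fwd_only <- drift[drift$direction == "forward", ]
  lam_avg <- action_spectrum(drift)$lambda_max
  lam_fwd <- action_spectrum(fwd_only)$lambda_max
  expect_lte(abs(lam_avg - 515), abs(lam_fwd - 515))
  expect_lt(abs(lam_avg - 515), 1)
})
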
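make_family <- function(perm = c(Cl = 1), noise = 0, seed = NA_integer_,
                        conditions = list(standard = standard_bath(),
                                          substituted = aspartate_bath())) {
  synthesize_iv_family(
    kinetic_params(permeabilities = perm),
    conditions = conditions,
    rec = recording_config(noise_sd = noise, seed = seed)
  )
}

fam0 <- make_family()

test_that("build_iv corrects voltages and orders them", {
  iv <- build_iv(fam0, "mean")
  expect_true(all(diff(iv$v_corr[iv$condition == "standard"]) > 0))
  expect_equal(iv$v_corr, iv$v_command - rep(
    c(henderson_ljp(pipette_solution(), standard_bath()),
      henderson_ljp(pipette_solution(), aspartate_bath()))[
        match(iv$condition, c("standard", "substituted"))], 1))
  # explicit zero LJP leaves commands untouched
  iv0 <- build_iv(fam0, "mean", ljp = 0)
  expect_equal(iv0$v_corr, iv0$v_command)
  # GHK currents increase with voltage
  expect_true(all(tapply(iv$current, iv$condition, function(x)
    all(diff(x) > 0))))
})

test_that("duplicate command voltages are rejected", {
  bad <- dplyr::bind_rows(fam0, fam0[1, ])
  expect_error(build_iv(bad, "mean"), "duplicate")
})

test_that("the noiseless pipeline reproduces generator GHK currents within 1%", {
  iv <- build_iv(fam0, "stationary")
  p <- kinetic_params()
  g <- simulate_gating(p, light_protocol())
  o_stat <- mean(g$O[g$time >= 950 & g$time <= 1050])
  for (cond in c("standard", "substituted")) {
    bath <- list(standard = standard_bath(),
                 substituted = aspartate_bath())[[cond]]
    sub <- iv[iv$condition == cond, ]
    er <- ghk_reversal(pipette_solution(), bath)
    pred <- p$g_scale * o_stat *
      acrtools:::.ghk_driving(sub$v_corr, pipette_solution(), bath,
                              p$permeabilities)
    expect_equal(sub$current, pred, tolerance = 0.01)
  }
})

test_that("reversal interpolation is exact on a line through a grid point", {
  iv <- structure(
    tibble::tibble(condition = "standard",
                   v_command = seq(-60, 60, 20),
                   v_corr = seq(-60, 60, 20),
                   current = seq(-60, 60, 20) * 2),
    class = c("acr_iv", "tbl_df", "tbl", "data.frame"), metric = "mean"
  )
  expect_equal(reversal_potential(iv)$e_rev, 0)
  iv$current <- iv$current + 100
  expect_equal(reversal_potential(iv)$e_rev, -50)
  iv$current <- abs(iv$current) + 1
  expect_error(reversal_potential(iv), "no sign change")
})

test_that("chloride-only reversal lands on the Nernst potential", {
  er <- reversal_potential(build_iv(fam0, "mean"))
  expect_equal(er$e_rev[er$condition == "standard"], -4.4215,
               tolerance = 0.1 / 4.4)
  expect_equal(er$e_rev[er$condition == "substituted"], 24.44,
               tolerance = 0.2 / 24)
})

test_that("reversal shift follows the standard-minus-substituted convention", {
  er <- reversal_potential(build_iv(fam0, "mean"))
  sh <- reversal_shift(er)
  expect_equal(sh$delta_e_rev,
               er$e_rev[er$condition == "standard"] -
                 er$e_rev[er$condition == "substituted"])
  expect_lt(sh$delta_e_rev, 0)
  # identical conditions shift by zero
  same <- reversal_shift(er[er$condition == "standard", ],
                         er[er$condition == "standard", ])
  expect_equal(same$delta_e_rev, 0)
  # metric mismatch is an input error
  er2 <- reversal_potential(build_iv(fam0, "peak"))
  expect_error(
    reversal_shift(er[er$condition == "standard", ],
                   er2[er2$condition == "substituted", ]),
    "metric mismatch"
  )
})

test_that("indistinguishable substitution produces no shift", {
  fam <- make_family(perm = c(Cl = 1, Asp = 1))
  sh <- reversal_shift(reversal_potential(build_iv(fam, "mean")))
  expect_lt(abs(sh$delta_e_rev), 0.2)
  expect_equal(fit_permeability_ratio(0)$ratio, 1, tolerance = 1e-6)
})

test_that("permeability-ratio fit inverts the generator setting", {
  sh <- reversal_shift(reversal_potential(build_iv(
    make_family(perm = c(Cl = 1, Asp = 0.2)), "mean")))
  fr <- fit_permeability_ratio(sh)
  expect_equal(fr$ratio, 0.2, tolerance = 0.02 / 0.2)
  # boundary: the zero-permeability shift maps to ratio 0
  shift0 <- ghk_reversal(pipette_solution(), standard_bath()) -
    ghk_reversal(pipette_solution(), aspartate_bath())
  expect_equal(fit_permeability_ratio(shift0)$ratio, 0)
  expect_error(fit_permeability_ratio(shift0 - 2), "no GHK solution")
})

test_that("autoplot renders traces, IV curves and spectra", {
  p1 <- ggplot2::autoplot(fam0$trace[[1]])
  expect_s3_class(p1, "ggplot")
  p2 <- ggplot2::autoplot(build_iv(fam0, "mean"))
  expect_s3_class(p2, "ggplot")
  sc <- synthesize_spectral_responses(kinetic_params(), seq(450, 600, 25))
  p3 <- ggplot2::autoplot(action_spectrum(sc))
  expect_s3_class(p3, "ggplot")
})
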
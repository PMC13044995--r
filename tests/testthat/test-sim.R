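test_that("the true-effect function matches the scenario definitions", {
  cfgI <- scenario_config("I", "beneficial")
  expect_equal(true_psi(cfgI, 1, c(0.3, 0.5), c(1, 0), k = 1), 0.5)
  expect_equal(true_psi(scenario_config("I", "adverse"), 0, 0.2, 0, k = 0), -0.5)

  cfgII <- scenario_config("II", "beneficial")
  expect_equal(true_psi(cfgII, 0, c(0.5, 1), c(1, 1), k = 1), -0.4 + 1.4 * 1)
  expect_equal(true_psi(scenario_config("II", "adverse"), 0, 0, 0, k = 0), -1)

  # scenario III at k = 2 with unit covariates and full exposure reaches the
  # calibrated support maximum 1.5 (discounted history sum 1 + 1/2)
  cfgIII <- scenario_config("III", "beneficial")
  expect_equal(true_psi(cfgIII, 1, c(1, 1, 1), c(1, 1, 1), k = 2),
               -0.3 + 0.4 + 0.44 * 1.5 + 0.44 + 0.3)
  expect_equal(true_psi(cfgIII, 0, c(0, 0, 0), c(0, 0, 0), k = 2), -0.3)

  # scenario IV: magnitude log(1.5) at a zero linear predictor, capped at
  # log(3) as the predictor grows
  cfgIV <- scenario_config("IV", "beneficial")
  L0 <- 0.45 / 0.66                        # makes x_0 = 0 for gender 0
  expect_equal(true_psi(cfgIV, 0, L0, 0, k = 0), log(1.5))
  big <- scenario_config("IV", "beneficial",
                         coefficients = c(psi1 = 0, psi2 = 0, psi3 = 100, psi4 = 0))
  expect_equal(true_psi(big, 0, 1, 0, k = 0), log(3), tolerance = 1e-6)
  adverse <- scenario_config("IV", "adverse")
  expect_equal(true_psi(adverse, 0, L0, 0, k = 0), -log(1.5))
})

test_that("generated effect ranges match the calibrated scenario supports", {
  p2 <- simulate_scenario(scenario_config("II", "beneficial", n = 3000, seed = 5))
  r2 <- range(attr(p2, "truth")$psi[p2$at_risk])
  expect_lt(abs(r2[2] - 1.0), 0.1)
  expect_lt(abs(r2[1] - (-0.4)), 0.1)

  p2a <- simulate_scenario(scenario_config("II", "adverse", n = 3000, seed = 5))
  r2a <- range(attr(p2a, "truth")$psi[p2a$at_risk])
  expect_lt(abs(r2a[1] - (-1.0)), 0.1)

  p3 <- simulate_scenario(scenario_config("III", "beneficial", n = 3000, seed = 5))
  expect_lt(abs(max(attr(p3, "truth")$psi[p3$at_risk]) - 1.5), 0.15)

  p4 <- simulate_scenario(scenario_config("IV", "beneficial", n = 3000, seed = 5))
  m4 <- abs(attr(p4, "truth")$psi[p4$at_risk])
  expect_lt(abs(min(m4) - log(1.5)), 0.05)
  expect_lt(max(m4), log(3))
})

test_that("censoring calibration hits its target and rejects infeasible ones", {
  cfg <- scenario_config("I", "beneficial")
  rate <- calibrate_censoring(cfg, n = 5000)
  expect_lt(abs(attr(rate, "achieved") - 0.40), 0.02)
  expect_error(calibrate_censoring(cfg, target = 0.001, n = 2000),
               "infeasible-target")
})

test_that("simulation is a pure function of the config", {
  cfg <- scenario_config("I", "beneficial", n = 200, seed = 33, censor_rate = 0.1)
  p1 <- simulate_scenario(cfg)
  p2 <- simulate_scenario(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_identical(attr(p1, "truth")$T0, attr(p2, "truth")$T0)
})

test_that("the generator produces genuine time-varying confounding", {
  pan <- simulate_scenario(scenario_config("I", "beneficial", n = 3000, seed = 35))
  at01 <- pan$at_risk[, 1] & pan$at_risk[, 2]
  # exposure responds to the current confounder
  expect_gt(abs(cor(pan$covariates$L[, 1], pan$A[, 1])), 0.05)
  # and the confounder responds to past exposure
  expect_gt(abs(cor(pan$A[at01, 1], pan$covariates$L[at01, 2])), 0.05)
})

test_that("outcome generation is rank-preserving within exposure strata", {
  pan <- simulate_scenario(scenario_config("I", "beneficial", n = 500, seed = 37,
                                           censor_rate = 0))
  truth <- attr(pan, "truth")
  path <- apply(ifelse(is.na(pan$A), 9, pan$A), 1, paste, collapse = "")
  for (g in split(seq_along(path), path)) {
    if (length(g) < 2) next
    expect_equal(order(truth$T0[g]), order(truth$Y[g]))
  }
})

test_that("the null scenario is effect-free with randomized exposure", {
  pan <- simulate_scenario(scenario_config("null", n = 2000, seed = 39,
                                           censor_rate = 0.05))
  truth <- attr(pan, "truth")
  expect_true(all(truth$psi == 0))
  expect_lt(abs(mean(pan$A, na.rm = TRUE) - 0.5), 0.05)
  expect_equal(truth$T0, truth$Y)
})

test_that("config validation rejects bad inputs", {
  expect_error(scenario_config("V"), "arg")
  expect_error(scenario_config("I", n = 0), "n must be")
  expect_error(scenario_config("I", coefficients = c(psi1 = NaN)), "finite")
})
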
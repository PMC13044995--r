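test_that("the score statistic reproduces a hand-computed two-record example", {
  # one visit at t_0 = 0, end of study 10; with psi = 0 the recensored times
  # X equal the observed times (2, 4) and the batch C is 10, so with the
  # recensored time as test function and p-hat = 1/2 the score is
  # 2 * (1 - 0.5) + 4 * (0 - 0.5) = -1
  s1 <- visit_schedule(0, 10)
  pan <- make_panel(list(list(T = 2, event = 1, A = 1),
                         list(T = 4, event = 1, A = 0)), schedule = s1)
  fit <- fit_propensity(pan, terms = character(0))
  expect_equal(unname(fit$p[, 1]), c(0.5, 0.5))
  sc <- score_statistic(pan, fit, 0, g_fun = "X")
  expect_equal(sc$S, -1)
  expect_equal(sc$U, matrix(c(1, -2), 2, 1))
})

test_that("perfect exposure predictions zero the score", {
  pan <- make_panel(list(list(T = 5, event = 1, A = c(1, 0, 1)),
                         list(T = 3, event = 1, A = c(0, 1)),
                         list(T = 6, event = 0, A = c(1, 1, 0))))
  fit <- manual_propensity(pan, pmin(pmax(pan$A, 1e-6), 1 - 1e-6))
  sc <- score_statistic(pan, fit, 0.3)
  expect_lt(max(abs(sc$S)), 1e-4)
})

test_that("a constant test function inherits the zero-sum of logistic residuals", {
  # identical follow-up and events make X identical across subjects, so
  # G is constant and S reduces to G * sum(residuals) = 0 at the MLE
  pan <- make_panel(list(list(T = 5, event = 1, A = c(1, 0, 1)),
                         list(T = 5, event = 1, A = c(0, 1, 0)),
                         list(T = 5, event = 1, A = c(1, 1, 0)),
                         list(T = 5, event = 1, A = c(0, 0, 1))))
  fit <- fit_propensity(pan, terms = character(0))
  sc <- score_statistic(pan, fit, 0, g_fun = "X")
  expect_lt(abs(sc$S), 1e-9)
})

test_that("grid search recovers the constant effect of a seeded simulation", {
  ests <- sapply(c(201, 203), function(s) {
    cfg <- scenario_config("I", "beneficial", n = 3000, seed = s)
    pan <- simulate_scenario(cfg)
    snaftm(pan, "gest1d")$estimate
  })
  expect_true(all(ests >= 0.4 & ests <= 0.6))
})

test_that("the test statistic profile is non-negative with a well-shaped confidence set", {
  cfg <- scenario_config("I", "beneficial", n = 1500, seed = 31)
  pan <- simulate_scenario(cfg)
  fit <- snaftm(pan, "gest1d", step = 0.02)
  expect_true(all(fit$trace$statistic >= 0))
  expect_true(fit$conf_int[1] <= fit$estimate && fit$estimate <= fit$conf_int[2])
  expect_equal(coef(fit), fit$estimate)
  expect_equal(confint(fit), fit$conf_int)
})

test_that("a null simulation gives an estimate near zero with a covering confidence set", {
  cfg <- scenario_config("null", n = 3000, seed = 601)
  pan <- simulate_scenario(cfg)
  fit <- snaftm(pan, "gest1d")
  expect_lt(abs(fit$estimate), 0.1)
  expect_true(fit$conf_int[1] <= 0 && 0 <= fit$conf_int[2])
})

test_that("unidentified and misspecified inputs raise the documented errors", {
  allzero <- make_panel(list(list(T = 5, event = 1, A = c(0, 0, 0)),
                             list(T = 5, event = 1, A = c(0, 0, 0))))
  expect_error(snaftm(allzero, "gest1d",
                      propensity = manual_propensity(allzero, 0.5)),
               "unidentified")
  pan <- make_panel(list(list(T = 5, event = 1, A = c(1, 0, 1)),
                         list(T = 5, event = 1, A = c(0, 1, 0)),
                         list(T = 3, event = 1, A = c(1, 0))))
  pf <- manual_propensity(pan, 0.5)
  expect_error(snaftm(pan, "gest2d", propensity = pf, modifier = "L"),
               "collinearity")  # helper panels carry constant L = 0.5
  expect_error(snaftm(pan, "gest1d", propensity = pf, grid = c(1, -1)),
               "grid")
  expect_error(snaftm(pan, "gest1d", propensity = pf, step = 0),
               "grid")
  expect_error(score_statistic(pan, pf, c(0.1, 0.2)), "modifier")
  expect_error(score_statistic(pan, pf, 0.1, modifier = "L"), "1-d")
})

test_that("two-dimensional grid search recovers a linear effect modification", {
  ests <- sapply(c(81, 82), function(s) {
    cfg <- scenario_config("II", "beneficial", n = 3000, seed = s)
    pan <- simulate_scenario(cfg)
    snaftm(pan, "gest2d", modifier = "L", grid = c(-2, 2), step = 0.1)$estimate
  })
  m <- rowMeans(ests)   # generating coefficients: intercept -0.4, slope 1.4
  expect_lt(abs(m[1] - (-0.4)), 0.2)
  expect_lt(abs(m[2] - 1.4), 0.2)
})

test_that("a spurious modifier gets a near-zero second coefficient", {
  cfg <- scenario_config("I", "beneficial", n = 3000, seed = 78)
  pan <- simulate_scenario(cfg)
  fit <- snaftm(pan, "gest2d", modifier = "gender", step = 0.05)
  expect_lt(abs(fit$estimate[2]), 0.2)
  expect_lt(abs(fit$estimate[1] - 0.5), 0.2)
})
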
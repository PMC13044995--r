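test_that("null copies equal to the observed exposure reproduce the observed statistics", {
  cfg <- scenario_config("I", "beneficial", n = 60, seed = 23, censor_rate = 0.05)
  pan <- simulate_scenario(cfg)
  M <- 4
  draws <- array(rep(pan$A, M), c(dim(pan$A), M))
  st <- mimic_statistics(pan, 0.4, draws, k = 1)
  for (m in 1:M) expect_equal(unname(st$null[m, ]), unname(st$observed))
})

test_that("degenerate outputs get zero correlation by convention", {
  # every subject censored at the end of study with no exposure effect: the
  # counterfactual times all equal the recensoring threshold, so X is
  # constant and the smoothed indicator is identically zero
  pan <- make_panel(list(list(T = 6, event = 0, A = c(1, 0, 1)),
                         list(T = 6, event = 0, A = c(0, 1, 0)),
                         list(T = 6, event = 0, A = c(1, 1, 1))))
  draws <- array(rep(pan$A, 3), c(dim(pan$A), 3))
  st <- mimic_statistics(pan, 0, draws, k = 0)
  expect_equal(unname(st$observed), c(0, 0))
  expect_true(all(st$null == 0))
})

test_that("null statistics concentrate around zero for an independent outcome", {
  cfg <- scenario_config("null", n = 400, seed = 25, censor_rate = 0.05)
  pan <- simulate_scenario(cfg)
  fit <- fit_propensity(pan, terms = character(0))
  draws <- draw_null_exposures(fit, 500, seed = 3)
  st <- mimic_statistics(pan, 0, draws, k = 0)
  expect_lt(abs(mean(st$null[, "X"])), 0.05)
  expect_lt(abs(mean(st$null[, "delta_star"])), 0.05)
})

test_that("the mimic loss reproduces the printed micro-example", {
  # one channel with observed statistic 0.3 and null mean 0.1, the other
  # degenerate, no variance penalty: 100 * |0.1 - 0.3| = 20
  x <- c(1, 2, 3, 4, 5)
  u <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  w <- c(1, -1, 0, 1, -1)
  w <- w - mean(w) - sum(w * u) * u
  v <- w / sqrt(sum(w^2))
  a_obs <- 0.3 * u + sqrt(1 - 0.09) * v     # cor(a_obs, x) = 0.3 exactly
  a_null <- 0.1 * u + sqrt(1 - 0.01) * v    # cor(a_null, x) = 0.1 exactly
  expect_equal(cor(a_obs, x), 0.3)
  expect_equal(cor(a_null, x), 0.1)
  vl <- snaftm:::.ge_mimic_visit(a_obs, cbind(a_null, a_null), X = x,
                                 Dstar = rep(0, 5), want_grad = FALSE)
  expect_equal(100 * vl$loss, 20)
})

test_that("the variance penalty enters linearly", {
  # with no exposed intervals the counterfactual outputs are free of psi, so
  # only the penalty changes between two psi matrices
  pan <- make_panel(list(list(T = 5, event = 1, A = c(0, 0, 0)),
                         list(T = 3, event = 1, A = c(0, 0)),
                         list(T = 4.5, event = 0, A = c(0, 0, 0)),
                         list(T = 2.5, event = 1, A = c(0, 0))))
  draws <- array(0, c(4, 3, 2))
  psi0 <- matrix(0.2, 4, 3)
  psi1 <- psi0
  psi1[, 1] <- c(-0.1, 0.1, 0.3, 0.5)      # sample variance at visit 0
  v <- stats::var(psi1[, 1])
  # only two subjects reach the last visit, which is skipped with a warning
  expect_warning(l0 <- ge_mimic_loss(pan, psi0, draws, gamma1 = 100, gamma2 = 10),
                 "skipped")
  expect_warning(l1 <- ge_mimic_loss(pan, psi1, draws, gamma1 = 100, gamma2 = 10),
                 "skipped")
  expect_equal(as.numeric(l1 - l0), 10 * v, tolerance = 1e-12)
  # the printed increment: adding 0.05 of variance costs 0.5 at gamma2 = 10
  expect_equal(10 * 0.05, 0.5)
})

test_that("the mimic loss gradient matches finite differences away from the batch-minimum subject", {
  cfg <- scenario_config("II", "beneficial", n = 12, seed = 3, censor_rate = 0.1)
  pan <- simulate_scenario(cfg)
  pf <- fit_propensity(pan, terms = "L")
  draws <- draw_null_exposures(pf, 20, seed = 9)
  n <- n_subjects(pan); K1 <- pan$schedule$K + 1
  set.seed(42)
  psi <- matrix(rnorm(n * K1, 0, 0.3), n, K1)
  an <- snaftm:::.ge_mimic_eval(pan, psi, draws, 1:n, 100, 10, TRUE)
  Ccand <- snaftm:::.cf_Ccand(pan, -psi)
  argmins <- unique(sapply(1:K1, function(k) {
    rk <- which(pan$at_risk[, k]); rk[which.min(Ccand[rk, k])]
  }))
  fn <- function(p) snaftm:::.ge_mimic_eval(pan, p, draws, 1:n, 100, 10, FALSE)$loss
  eps <- 1e-6
  set.seed(8)
  pts <- cbind(sample(setdiff(1:n, argmins), 5, replace = TRUE), sample(K1, 5, replace = TRUE))
  for (j in 1:5) {
    p1 <- psi; p1[pts[j, 1], pts[j, 2]] <- p1[pts[j, 1], pts[j, 2]] + eps
    p2 <- psi; p2[pts[j, 1], pts[j, 2]] <- p2[pts[j, 1], pts[j, 2]] - eps
    num <- (fn(p1) - fn(p2)) / (2 * eps)
    expect_equal(an$dpsi[pts[j, 1], pts[j, 2]], num, tolerance = 1e-4)
  }
})

test_that("observed statistics are exchangeable with the null copies at the truth", {
  inside <- 0L; total <- 0L
  for (s in 1:10) {
    cfg <- scenario_config("I", "beneficial", n = 1500, seed = 700 + s)
    pan <- simulate_scenario(cfg)
    fit <- fit_propensity(pan)
    draws <- draw_null_exposures(fit, 100, seed = s)
    for (k in 0:2) {
      st <- mimic_statistics(pan, 0.5, draws, k = k)
      for (ch in c("X", "delta_star")) {
        q <- stats::quantile(st$null[, ch], c(0.025, 0.975))
        inside <- inside + (st$observed[ch] >= q[1] && st$observed[ch] <= q[2])
        total <- total + 1L
      }
    }
  }
  expect_gte(inside / total, 0.9)
})

test_that("mimic training is reproducible and stable in the number of null copies", {
  cfg <- scenario_config("I", "beneficial", n = 2000, seed = 27)
  pan <- simulate_scenario(cfg)
  pf <- fit_propensity(pan)
  f1 <- snaftm(pan, "ge_mimic", propensity = pf, seed = 4, M = 100)
  f2 <- snaftm(pan, "ge_mimic", propensity = pf, seed = 4, M = 100)
  expect_identical(f1$estimate, f2$estimate)
  f3 <- snaftm(pan, "ge_mimic", propensity = pf, seed = 4, M = 200)
  expect_lt(abs(f1$estimate - f3$estimate), 0.05)
  expect_lt(abs(f1$estimate - 0.5), 0.25)
})
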
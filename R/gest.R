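#' Score statistic for a candidate causal parameter
#'
#' Evaluates the g-estimation score
#' \eqn{S(\psi) = \sum_i \sum_{k \le V_i} G_{ik}(\psi)\,(A_{ik} - \hat p_{ik})}
#' where the test function \eqn{G} is built from the artificially censored
#' counterfactual outputs at the candidate \eqn{\psi}. At the true parameter
#' and a correctly specified exposure model the score has mean zero, because
#' the counterfactual untreated outcome is conditionally independent of the
#' exposure given history.
#'
#' @param panel a `snaftm_panel`.
#' @param fit a `snaftm_propensity` for the same panel.
#' @param psi candidate parameter: scalar for the 1-d model, or length-2
#'   `(psi1, psi2)` with `modifier` for the 2-d model
#'   \eqn{\psi_{ik} = \psi_1 + \psi_2\, \mathrm{modifier}_{ik}}.
#' @param g_fun which counterfactual output forms `G`: the smoothed
#'   artificial-censoring indicator `"delta_star"` (default, optimizer
#'   friendly), the hard indicator `"delta"`, or the recensored time `"X"`.
#' @param modifier covariate column name for the 2-d model.
#' @return A list with the score vector `S` (length = dim of `psi`) and the
#'   matrix `U` of per-subject score contributions.
#' @export
score_statistic <- function(panel, fit, psi, g_fun = c("delta_star", "delta", "X"),
                            modifier = NULL) {
  stopifnot(inherits(panel, "snaftm_panel"), inherits(fit, "snaftm_propensity"))
  g_fun <- match.arg(g_fun)
  nu <- length(psi)
  if (nu == 2L && is.null(modifier))
    stop("specification error: 2-d psi requires a modifier column")
  if (nu == 1L && !is.null(modifier))
    stop("specification error: modifier given but psi is 1-d")
  if (!nu %in% 1:2) stop("specification error: psi must have length 1 or 2")

  n <- length(panel$subject_id)
  K <- panel$schedule$K
  if (nu == 2L) {
    mod <- .modifier_matrix(panel, modifier)
    psi_mat <- psi[1L] + psi[2L] * mod
  } else {
    psi_mat <- .as_phi_matrix(panel, psi)  # constant matrix
  }
  phi_mat <- -psi_mat
  res <- residuals(fit, panel)
  H_all <- .cf_H(panel, phi_mat)$H
  Ccand <- .cf_Ccand(panel, phi_mat)

  U <- matrix(0, n, nu)
  for (k in 0:K) {
    cf <- .cf_visit(panel, phi_mat, k, seq_len(n), H_all = H_all, Ccand = Ccand)
    g <- switch(g_fun, delta_star = cf$delta_star, delta = cf$delta, X = cf$X)
    rk <- res[cf$rows, k + 1L]
    U[cf$rows, 1L] <- U[cf$rows, 1L] + g * rk
    if (nu == 2L) {
      gm <- g * .modifier_matrix(panel, modifier)[cf$rows, k + 1L]
      U[cf$rows, 2L] <- U[cf$rows, 2L] + gm * rk
    }
  }
  list(S = colSums(U), U = U)
}

.modifier_matrix <- function(panel, modifier) {
  if (!modifier %in% names(panel$covariates))
    stop("specification error: unknown modifier column '", modifier, "'")
  panel$cov_fill[[modifier]]
}

# chi-square test statistic T(psi) = S' V^{-1} S, V = sum_i U_i U_i'
.gest_T <- function(sc) {
  V <- crossprod(sc$U)
  Ti <- tryCatch(drop(t(sc$S) %*% solve(V, sc$S)), error = function(e) NA_real_)
  if (!is.finite(Ti))
    stop("rank-deficiency error: singular score covariance ",
         "(test function carries no information)")
  Ti
}

# 1-d grid-search g-estimation (test inversion)
.fit_gest1d <- function(panel, fit, grid = c(-1, 1), step = 0.01,
                        g_fun = "delta_star", level = 0.95) {
  .check_identifiable(panel)
  .check_grid(grid, step)
  psis <- seq(grid[1L], grid[2L], by = step)
  Tvals <- vapply(psis, function(p)
    .gest_T(score_statistic(panel, fit, p, g_fun = g_fun)), numeric(1L))
  pick <- .grid_argmin(psis, Tvals)
  crit <- stats::qchisq(level, df = 1)
  inside <- psis[Tvals <= crit]
  ci <- if (length(inside)) range(inside) else c(psis[pick], psis[pick])
  .new_snaftm(
    method = "gest1d",
    estimate = psis[pick],
    conf_int = ci,
    trace = data.frame(psi = psis, statistic = Tvals),
    config = list(grid = grid, step = step, g_fun = g_fun, level = level),
    panel = panel
  )
}

# 2-d grid search with psi_ik = psi1 + psi2 * modifier_ik
.fit_gest2d <- function(panel, fit, grid = c(-1, 1), step = 0.05,
                        modifier, g_fun = "delta_star", level = 0.95) {
  .check_identifiable(panel)
  .check_grid(grid, step)
  if (missing(modifier) || is.null(modifier))
    stop("specification error: gest2d requires a modifier column")
  mod <- .modifier_matrix(panel, modifier)
  if (stats::sd(mod[panel$at_risk]) < 1e-12)
    stop("collinearity error: modifier is constant on the at-risk records")
  psis <- seq(grid[1L], grid[2L], by = step)
  gridpts <- expand.grid(psi1 = psis, psi2 = psis)
  Tvals <- vapply(seq_len(nrow(gridpts)), function(j) {
    .gest_T(score_statistic(panel, fit,
                            c(gridpts$psi1[j], gridpts$psi2[j]),
                            g_fun = g_fun, modifier = modifier))
  }, numeric(1L))
  norms <- sqrt(gridpts$psi1^2 + gridpts$psi2^2)
  pick <- order(Tvals, norms, gridpts$psi1, gridpts$psi2)[1L]
  crit <- stats::qchisq(level, df = 2)
  inside <- Tvals <= crit
  ci <- if (any(inside)) {
    rbind(psi1 = range(gridpts$psi1[inside]), psi2 = range(gridpts$psi2[inside]))
  } else {
    rbind(psi1 = rep(gridpts$psi1[pick], 2), psi2 = rep(gridpts$psi2[pick], 2))
  }
  .new_snaftm(
    method = "gest2d",
    estimate = c(psi1 = gridpts$psi1[pick], psi2 = gridpts$psi2[pick]),
    conf_int = ci,
    trace = cbind(gridpts, statistic = Tvals),
    config = list(grid = grid, step = step, g_fun = g_fun, level = level,
                  modifier = modifier),
    panel = panel
  )
}

.check_grid <- function(grid, step) {
  if (length(grid) != 2L || grid[1L] >= grid[2L])
    stop("grid error: lower bound must be below upper bound")
  if (step <= 0) stop("grid error: step must be positive")
  if ((grid[2L] - grid[1L]) / step > 1e6) stop("grid error: grid too large")
}

.check_identifiable <- function(panel) {
  a <- panel$A[panel$at_risk]
  if (all(a == 0))
    stop("unidentified: no exposed person-visits in the data")
  if (all(a == 1))
    stop("unidentified: no unexposed person-visits in the data")
}

# tie-break toward smallest |psi|, then smallest psi
.grid_argmin <- function(psis, Tvals) {
  order(Tvals, abs(psis), psis)[1L]
}
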
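# Correlation statistics and their analytic gradients, plus the chain rule
# through the artificial-censoring transform. The batch minimum C is treated
# as a constant in the gradients: it is a single order statistic of the batch
# and moving it contributes one subject's subgradient out of the whole batch,
# which is negligible and keeps the recensoring threshold stable during
# optimization.

# Pearson correlation with the degenerate-variance convention cor(.) = 0
.cor0 <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx < 1e-12 || sy < 1e-12) return(0)
  stats::cor(x, y)
}

# rho = cor(a, y) and d rho / d y_i; zero-variance convention gives rho = 0
# with a zero gradient
.cor_grad <- function(a, y) {
  n <- length(y)
  sa <- stats::sd(a); sy <- stats::sd(y)
  if (n < 3L || sa < 1e-12 || sy < 1e-12)
    return(list(rho = 0, dy = rep(0, n)))
  ac <- a - mean(a); yc <- y - mean(y)
  rho <- sum(ac * yc) / ((n - 1) * sa * sy)
  dy <- ac / ((n - 1) * sa * sy) - rho * yc / ((n - 1) * sy^2)
  list(rho = rho, dy = dy)
}

# mean over null copies m of rho_m = cor(atil[, m], y), and the gradient of
# that mean with respect to y. Degenerate columns contribute rho_m = 0.
.cor_grad_null <- function(atil, y) {
  n <- length(y); M <- ncol(atil)
  sy <- stats::sd(y)
  if (n < 3L || sy < 1e-12)
    return(list(rho_bar = 0, dy = rep(0, n)))
  yc <- y - mean(y)
  ac <- sweep(atil, 2, colMeans(atil), "-")
  sm <- apply(atil, 2, stats::sd)
  ok <- is.finite(sm) & sm > 1e-12
  if (!any(ok)) return(list(rho_bar = 0, dy = rep(0, n)))
  rhos <- rep(0, M)
  rhos[ok] <- colSums(ac[, ok, drop = FALSE] * yc) / ((n - 1) * sm[ok] * sy)
  rho_bar <- sum(rhos) / M
  term1 <- rowSums(sweep(ac[, ok, drop = FALSE], 2, sm[ok], "/")) /
    (M * (n - 1) * sy)
  term2 <- rho_bar * yc / ((n - 1) * sy^2)
  list(rho_bar = rho_bar, dy = term1 - term2)
}

.row_cumsum <- function(m) {
  if (ncol(m) == 1L) return(m)
  out <- t(apply(m, 1L, cumsum))
  if (nrow(m) == 1L) out <- matrix(out, 1L)
  out
}

# sample variance of v and its gradient
.var_grad <- function(v) {
  n <- length(v)
  if (n < 2L) return(list(v = 0, dv = rep(0, n)))
  list(v = stats::var(v), dv = 2 * (v - mean(v)) / (n - 1))
}

# Evaluate a per-visit correlation loss over the batch and chain its gradient
# back to the psi matrix.
#
# visit_fn(k, cf, rows) must return list(loss_k, gX, gD): the visit loss and
# the gradients with respect to X and delta_star over cf$rows (or NULL to
# skip the visit). Returns total loss (correlation part and penalty part kept
# separate), per-visit breakdown, and dL/dpsi when want_grad.
.corr_loss_engine <- function(panel, psi_mat, rows, visit_fn,
                              gamma1, gamma2, want_grad = FALSE,
                              min_records = 3L) {
  phi_mat <- -psi_mat
  hh <- .cf_H(panel, phi_mat)
  Ccand <- .cf_Ccand(panel, phi_mat)
  K <- panel$schedule$K
  n <- length(panel$subject_id)
  G_mat <- if (want_grad) matrix(0, n, K + 1L) else NULL
  dpsi <- if (want_grad) matrix(0, n, K + 1L) else NULL
  breakdown <- data.frame(visit = 0:K, corr_loss = NA_real_, psi_var = NA_real_)
  total_corr <- 0
  total_pen <- 0
  for (k in 0:K) {
    rk_rows <- rows[panel$at_risk[rows, k + 1L]]
    if (length(rk_rows) < min_records) {
      warning("visit ", k, " skipped: fewer than ", min_records,
              " at-risk records in the batch")
      next
    }
    cf <- .cf_visit(panel, phi_mat, k, rk_rows, H_all = hh$H, Ccand = Ccand)
    vl <- visit_fn(k, cf, cf$rows)
    if (is.null(vl)) next
    vg <- .var_grad(psi_mat[cf$rows, k + 1L])
    breakdown$corr_loss[k + 1L] <- vl$loss
    breakdown$psi_var[k + 1L] <- vg$v
    total_corr <- total_corr + vl$loss
    total_pen <- total_pen + vg$v
    if (want_grad) {
      uncens <- cf$delta == 1L
      dH <- gamma1 * (vl$gX * uncens + vl$gD * (-1 / cf$C) * uncens)
      G_mat[cbind(cf$rows, k + 1L)] <- G_mat[cbind(cf$rows, k + 1L)] + dH
      dpsi[cbind(cf$rows, k + 1L)] <- dpsi[cbind(cf$rows, k + 1L)] +
        gamma2 * vg$dv
    }
  }
  if (want_grad) {
    # dH(k)/dpsi_u = -A_u E_u for every evaluation visit k <= u, so the
    # H-channel gradient is a running sum of the per-visit terms
    cumG <- .row_cumsum(G_mat)
    dpsi <- dpsi + (-panel$A_fill * hh$E) * cumG
    dpsi[is.na(dpsi)] <- 0
  }
  list(loss = gamma1 * total_corr + gamma2 * total_pen,
       corr = total_corr, gamma_corr = gamma1 * total_corr,
       penalty = total_pen,
       breakdown = breakdown, dpsi = dpsi)
}
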
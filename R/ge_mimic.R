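#' Observed and null dependence statistics at a visit
#'
#' Computes the observed Pearson correlations between the exposure at visit
#' `k` and each artificially censored counterfactual output
#' \eqn{(X, \Delta^*)}, together with the same statistics recomputed with
#' each null exposure copy substituted for the observed exposure. Under the
#' conditional-independence null the observed statistic is exchangeable with
#' the null copies. Degenerate-variance correlations are 0 by convention.
#'
#' @param panel a `snaftm_panel`.
#' @param psi causal parameters (scalar or subjects-by-visits matrix,
#'   reporting convention).
#' @param draws null exposure array from [draw_null_exposures()].
#' @param k 0-based visit index.
#' @param subset optional batch rows.
#' @return A list with `observed` (named length-2 vector: `X`, `delta_star`)
#'   and `null` (M-by-2 matrix of per-copy statistics).
#' @export
mimic_statistics <- function(panel, psi, draws, k, subset = NULL) {
  stopifnot(inherits(panel, "snaftm_panel"))
  K <- panel$schedule$K
  if (k < 0 || k > K) stop("visit index out of range")
  if (!identical(dim(draws)[1:2], dim(panel$A)))
    stop("alignment error: null draws do not match the panel")
  psi_mat <- .as_phi_matrix(panel, psi)
  rows <- if (is.null(subset)) seq_along(panel$subject_id) else subset
  cf <- .cf_visit(panel, -psi_mat, k, rows)
  a <- panel$A[cbind(cf$rows, k + 1L)]
  atil <- draws[cf$rows, k + 1L, , drop = FALSE]
  atil <- matrix(atil, nrow = length(cf$rows))
  if (anyNA(atil)) stop("alignment error: null draws missing on at-risk records")
  M <- ncol(atil)
  null_stats <- cbind(
    X = vapply(seq_len(M), function(m) .cor0(atil[, m], cf$X), numeric(1L)),
    delta_star = vapply(seq_len(M), function(m) .cor0(atil[, m], cf$delta_star),
                        numeric(1L))
  )
  list(observed = c(X = .cor0(a, cf$X), delta_star = .cor0(a, cf$delta_star)),
       null = null_stats)
}

#' Null-mimic network loss
#'
#' Per visit \eqn{k} the loss is the absolute difference between the observed
#' dependence statistic and the mean of its null distribution, summed over
#' the two output channels:
#' \deqn{\mathcal{L}_k = |\bar\rho^{null}_{k,X} - \rho_{k,X}| +
#'   |\bar\rho^{null}_{k,\Delta^*} - \rho_{k,\Delta^*}|,}
#' with the same \eqn{\gamma_1/\gamma_2} weighting and variance penalty as
#' the score loss. The null exposure copies are fixed data; gradients flow
#' only through the dependence of \eqn{(X, \Delta^*)} on \eqn{\psi}.
#'
#' @inheritParams ge_score_loss
#' @param draws null exposure array from [draw_null_exposures()].
#' @return Scalar loss with attribute `"breakdown"`.
#' @export
ge_mimic_loss <- function(panel, psi, draws, gamma1 = 100, gamma2 = 10,
                          subset = NULL, min_records = 3L) {
  stopifnot(inherits(panel, "snaftm_panel"))
  psi_mat <- .as_phi_matrix(panel, psi)
  rows <- if (is.null(subset)) seq_along(panel$subject_id) else subset
  out <- .ge_mimic_eval(panel, psi_mat, draws, rows, gamma1, gamma2,
                        want_grad = FALSE, min_records = min_records)
  structure(out$loss, breakdown = out$breakdown)
}

# visit loss |mean_m rho_m(X) - rho(X)| + |mean_m rho_m(D*) - rho(D*)|
.ge_mimic_visit <- function(a, atil, X, Dstar, want_grad) {
  ox <- .cor_grad(a, X)
  od <- .cor_grad(a, Dstar)
  nx <- .cor_grad_null(atil, X)
  nd <- .cor_grad_null(atil, Dstar)
  dx <- nx$rho_bar - ox$rho
  dd <- nd$rho_bar - od$rho
  loss <- abs(dx) + abs(dd)
  if (!want_grad) return(list(loss = loss, gX = NULL, gD = NULL))
  list(loss = loss,
       gX = sign(dx) * (nx$dy - ox$dy),
       gD = sign(dd) * (nd$dy - od$dy))
}

.ge_mimic_eval <- function(panel, psi_mat, draws, rows, gamma1, gamma2,
                           want_grad, min_records = 3L) {
  .corr_loss_engine(
    panel, psi_mat, rows,
    visit_fn = function(k, cf, batch_rows) {
      a <- panel$A[cbind(batch_rows, k + 1L)]
      atil <- matrix(draws[batch_rows, k + 1L, , drop = FALSE],
                     nrow = length(batch_rows))
      .ge_mimic_visit(a, atil, cf$X, cf$delta_star, want_grad)
    },
    gamma1 = gamma1, gamma2 = gamma2, want_grad = want_grad,
    min_records = min_records
  )
}

# gradient-trained counterfactual network with the null-mimic loss
.fit_ge_mimic <- function(panel, fit, M = 100, hidden = 16, psi_max = 2,
                          gamma1 = 100, gamma2 = 10, lr = 1e-2,
                          epochs = 200, patience = 20, inputs = NULL,
                          split = c(0.7, 0.2, 0.1), seed = 1,
                          min_records = 3L) {
  if (M < 1) stop("parameter error: M must be >= 1")
  draws <- draw_null_exposures(fit, M, seed = seed + 10000L)
  loss_fn <- function(psi_mat, rows, want_grad)
    .ge_mimic_eval(panel, psi_mat, draws, rows, gamma1, gamma2, want_grad,
                   min_records = min_records)
  out <- .fit_counterfactual_net(panel, loss_fn, method = "ge_mimic",
                                 hidden = hidden, psi_max = psi_max,
                                 gamma1 = gamma1, gamma2 = gamma2, lr = lr,
                                 epochs = epochs, patience = patience,
                                 inputs = inputs, split = split, seed = seed)
  out$config$M <- M
  out
}
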
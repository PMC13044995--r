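#' Score-based network loss
#'
#' Per visit \eqn{k}, over the at-risk records of the batch, the loss is the
#' sum of the absolute Pearson correlations between the exposure-model
#' residuals \eqn{r_k} and each artificially censored counterfactual output:
#' \deqn{\mathcal{L}_k = |\rho(r_k, X_k)| + |\rho(r_k, \Delta^*_k)|,}
#' and the total objective adds a variance penalty on the individualized
#' parameters:
#' \eqn{\sum_k [\gamma_1 \mathcal{L}_k + \gamma_2\, \mathrm{var}_i(\hat\psi_{ik})]}.
#' At the true parameter, with a correctly specified exposure model, each
#' correlation has null magnitude \eqn{O(N^{-1/2})}. A correlation with a
#' zero-variance argument is defined as 0 (needed early in training when
#' \eqn{\Delta^*} can be identically zero). Visits with fewer than
#' `min_records` at-risk batch records are skipped with a warning.
#'
#' @param panel a `snaftm_panel`.
#' @param psi causal parameters in the reporting convention: scalar or
#'   subjects-by-visits matrix.
#' @param residuals residual matrix from [residuals.snaftm_propensity()].
#' @param gamma1,gamma2 loss weights (defaults 100 and 10).
#' @param subset subject rows forming the batch (default all).
#' @param min_records minimum at-risk batch records per visit.
#' @return Scalar loss with attribute `"breakdown"` (per-visit correlation
#'   loss and psi variance).
#' @export
ge_score_loss <- function(panel, psi, residuals, gamma1 = 100, gamma2 = 10,
                          subset = NULL, min_records = 3L) {
  stopifnot(inherits(panel, "snaftm_panel"))
  psi_mat <- .as_phi_matrix(panel, psi)
  rows <- if (is.null(subset)) seq_along(panel$subject_id) else subset
  out <- .ge_score_eval(panel, psi_mat, residuals, rows, gamma1, gamma2,
                        want_grad = FALSE, min_records = min_records)
  structure(out$loss, breakdown = out$breakdown)
}

# visit loss |cor(r, X)| + |cor(r, D*)| with gradients wrt X and D*
.ge_score_visit <- function(r, X, Dstar, want_grad) {
  cx <- .cor_grad(r, X)
  cd <- .cor_grad(r, Dstar)
  loss <- abs(cx$rho) + abs(cd$rho)
  if (!want_grad) return(list(loss = loss, gX = NULL, gD = NULL))
  list(loss = loss,
       gX = sign(cx$rho) * cx$dy,
       gD = sign(cd$rho) * cd$dy)
}

.ge_score_eval <- function(panel, psi_mat, res, rows, gamma1, gamma2,
                           want_grad, min_records = 3L) {
  .corr_loss_engine(
    panel, psi_mat, rows,
    visit_fn = function(k, cf, batch_rows) {
      .ge_score_visit(res[cbind(batch_rows, k + 1L)], cf$X, cf$delta_star,
                      want_grad)
    },
    gamma1 = gamma1, gamma2 = gamma2, want_grad = want_grad,
    min_records = min_records
  )
}

# gradient-trained counterfactual network with the score loss
.fit_ge_score <- function(panel, fit, hidden = 16, psi_max = 2,
                          gamma1 = 100, gamma2 = 10, lr = 1e-2,
                          epochs = 200, patience = 20, inputs = NULL,
                          split = c(0.7, 0.2, 0.1), seed = 1,
                          min_records = 3L) {
  res <- residuals(fit, panel)
  loss_fn <- function(psi_mat, rows, want_grad)
    .ge_score_eval(panel, psi_mat, res, rows, gamma1, gamma2, want_grad,
                   min_records = min_records)
  .fit_counterfactual_net(panel, loss_fn, method = "ge_score",
                          hidden = hidden, psi_max = psi_max,
                          gamma1 = gamma1, gamma2 = gamma2, lr = lr,
                          epochs = epochs, patience = patience,
                          inputs = inputs, split = split, seed = seed)
}

# one optimization run of the counterfactual network (Adam on the analytic
# gradient) with two guards against fitting sampling noise:
#
# * noise-floor stopping: under the conditional-independence null, a sample
#   Pearson correlation over n records has E|rho| = sqrt(2 / (pi n)), so the
#   correlation part of the training loss cannot be pushed below
#   gamma1 * sum_k 2 sqrt(2 / (pi n_k)) except by overfitting the realized
#   noise; the run stops the first time it reaches that floor and keeps the
#   parameters that reached it;
# * otherwise, early stopping and model selection use a trailing-window
#   average of the validation loss (the objective is noisy at the validation
#   sample size).
.train_net_once <- function(panel, loss_fn, x_list, hidden, psi_max, lr,
                            epochs, patience, rows_tr, rows_va, init_seed,
                            corr_floor = NULL) {
  params <- .rnn_init(ncol(x_list[[1L]]), hidden, init_seed)
  state <- .adam_init(params)
  best <- list(loss = Inf, params = params, floored = FALSE)
  wait <- 0L
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  for (ep in seq_len(epochs)) {
    fwd <- .rnn_forward(params, x_list)
    th <- tanh(fwd$z)
    psi_mat <- psi_max * th
    lg <- loss_fn(psi_mat, rows_tr, TRUE)
    if (!is.finite(lg$loss)) stop("training error: non-finite loss")
    if (!is.null(corr_floor) && ep > 1L && lg$gamma_corr <= corr_floor) {
      # the current parameters produced this loss; keep them and stop
      vloss <- loss_fn(psi_max * tanh(.rnn_forward(params, x_list)$z),
                       rows_va, FALSE)$loss
      trace <- rbind(trace, data.frame(epoch = ep, train_loss = lg$loss,
                                       val_loss = vloss))
      best <- list(loss = vloss, params = params, floored = TRUE)
      break
    }
    dZ <- lg$dpsi * psi_max * (1 - th * th)
    grads <- .rnn_backward(params, x_list, fwd, dZ)
    upd <- .adam_step(params, grads, state, lr = lr)
    params <- upd$params
    state <- upd$state

    fwd2 <- .rnn_forward(params, x_list)
    psi2 <- psi_max * tanh(fwd2$z)
    vloss <- loss_fn(psi2, rows_va, FALSE)$loss
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = lg$loss,
                                     val_loss = vloss))
    w <- min(nrow(trace), 5L)
    vsmooth <- mean(trace$val_loss[(nrow(trace) - w + 1L):nrow(trace)])
    if (vsmooth < best$loss - 1e-7) {
      best$loss <- vsmooth
      best$params <- params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(best = best, trace = trace)
}

# shared training loop for both network estimators; the non-convex
# correlation objective occasionally traps a single run in a poor basin, so
# the fit restarts from a few seeded initializations and keeps the restart
# with the best (smoothed) validation loss
.fit_counterfactual_net <- function(panel, loss_fn, method, hidden, psi_max,
                                    gamma1, gamma2, lr, epochs, patience,
                                    inputs, split, seed, restarts = 3L) {
  .check_identifiable(panel)
  n <- length(panel$subject_id)
  stopifnot(abs(sum(split) - 1) < 1e-8, length(split) == 3L)
  set.seed(seed)
  perm <- sample.int(n)
  n_tr <- max(1L, floor(split[1L] * n))
  n_va <- max(1L, floor(split[2L] * n))
  n_te <- n - n_tr - n_va
  if (n_te < 1L) stop("dataset too small for a train/validation/test split")
  rows_tr <- sort(perm[seq_len(n_tr)])
  rows_va <- sort(perm[n_tr + seq_len(n_va)])
  rows_te <- sort(perm[(n_tr + n_va + 1L):n])

  x_list <- .net_inputs(panel, inputs)
  n_k <- colSums(panel$at_risk[rows_tr, , drop = FALSE])
  n_k <- n_k[n_k >= 3L]
  corr_floor <- gamma1 * sum(2 * sqrt(2 / (pi * n_k)))
  runs <- lapply(seq_len(restarts), function(r) {
    .train_net_once(panel, loss_fn, x_list, hidden, psi_max, lr, epochs,
                    patience, rows_tr, rows_va,
                    init_seed = seed + 1000L * (r - 1L),
                    corr_floor = corr_floor)
  })
  # ensemble over restarts: average the per-record predictions of the runs
  # that reached the noise floor (all runs if none did); averaging the
  # restart ensemble damps initialization sensitivity of the non-convex fit
  floored <- vapply(runs, function(z) z$best$floored, logical(1L))
  keep <- if (any(floored)) which(floored) else seq_along(runs)
  psi_runs <- lapply(runs[keep], function(z)
    psi_max * tanh(.rnn_forward(z$best$params, x_list)$z))
  psi_final <- Reduce(`+`, psi_runs) / length(psi_runs)
  pick <- keep[which.min(vapply(runs[keep], function(z) z$best$loss,
                                numeric(1L)))]
  best <- runs[[pick]]$best
  trace <- runs[[pick]]$trace
  trace$restart <- pick
  psi_final[!panel$at_risk] <- NA_real_
  te_vals <- psi_final[rows_te, , drop = FALSE]
  te_at <- panel$at_risk[rows_te, , drop = FALSE]
  per_visit <- lapply(seq_len(ncol(te_vals)), function(j) {
    v <- te_vals[te_at[, j], j]
    if (!length(v)) return(c(mean = NA_real_, min = NA_real_, max = NA_real_))
    c(mean = mean(v), min = min(v), max = max(v))
  })
  per_visit <- do.call(rbind, per_visit)
  all_te <- te_vals[te_at]
  .new_snaftm(
    method = method,
    estimate = mean(all_te),
    conf_int = NULL,
    range = c(min(all_te), max(all_te)),
    per_visit = data.frame(visit = 0:(ncol(te_vals) - 1L), per_visit),
    psi = psi_final,
    split = list(train = rows_tr, validation = rows_va, test = rows_te),
    trace = trace,
    config = list(hidden = hidden, psi_max = psi_max, gamma1 = gamma1,
                  gamma2 = gamma2, lr = lr, epochs = epochs,
                  patience = patience, split = split, seed = seed),
    params = best$params,
    panel = panel
  )
}
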
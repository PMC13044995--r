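#' Fit the exposure mechanism (propensity model)
#'
#' Estimates \eqn{\Pr(A_k = 1 \mid \bar L_k, \bar A_{k-1})} on the at-risk
#' person-visit records, either by a pooled-over-visits logistic regression
#' (the classical choice, and the default used by G-estimation) or by a
#' recurrent network trained by cross-entropy with early stopping.
#'
#' For the logistic model, `terms` names the design columns: covariate names
#' from the panel plus the pseudo-terms `".A_prev"` (previous exposure, 0 at
#' the first visit) and `".visit"` (visit fixed effects). The default is all
#' covariates plus both pseudo-terms; an empty character vector fits an
#' intercept-only model whose fitted value is the overall exposure fraction.
#'
#' @param panel a `snaftm_panel`.
#' @param terms character vector of design terms (logistic) or input
#'   covariate names (recurrent); `NULL` for the default.
#' @param method `"logistic"` or `"recurrent"`.
#' @param hidden hidden-state size of the recurrent unit.
#' @param lr,epochs,patience optimizer settings for the recurrent fit.
#' @param val_frac fraction of subjects held out for early stopping.
#' @param seed integer seed controlling initialization and the validation
#'   split of the recurrent fit.
#' @return An object of class `snaftm_propensity` with the fitted probability
#'   matrix `p` (subjects by visits, `NA` off the at-risk set, clipped to
#'   `[1e-6, 1 - 1e-6]`), the `method` tag, and training metadata.
#' @export
fit_propensity <- function(panel, terms = NULL,
                           method = c("logistic", "recurrent"),
                           hidden = 16, lr = 1e-3, epochs = 200,
                           patience = 20, val_frac = 0.2, seed = 1) {
  stopifnot(inherits(panel, "snaftm_panel"))
  method <- match.arg(method)
  at <- panel$at_risk
  a_all <- panel$A[at]
  if (sum(at) < 2L)
    stop("degenerate data: fewer than two at-risk records")
  if (all(a_all == 1) || all(a_all == 0))
    stop("degenerate data: exposure does not vary")
  if (method == "logistic") .fit_propensity_glm(panel, terms)
  else .fit_propensity_rnn(panel, terms, hidden, lr, epochs, patience,
                           val_frac, seed)
}

# long at-risk design frame
.propensity_frame <- function(panel) {
  K1 <- panel$schedule$K + 1L
  at <- panel$at_risk
  idx <- which(at, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  A_prev <- cbind(0, panel$A[, -K1, drop = FALSE])
  df <- data.frame(.row = idx[, 1L], .k = idx[, 2L],
                   A = panel$A[idx], .A_prev = A_prev[idx],
                   .visit = factor(idx[, 2L] - 1L, levels = 0:(K1 - 1L)))
  for (cn in names(panel$covariates)) df[[cn]] <- panel$covariates[[cn]][idx]
  df
}

.fit_propensity_glm <- function(panel, terms) {
  df <- .propensity_frame(panel)
  if (is.null(terms))
    terms <- c(names(panel$covariates), ".A_prev", ".visit")
  if (".visit" %in% terms && length(unique(df$.visit)) < 2L)
    terms <- setdiff(terms, ".visit")
  rhs <- if (length(terms) == 0L) "1" else
    paste(sprintf("`%s`", terms), collapse = " + ")
  fml <- stats::as.formula(paste("A ~", rhs))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (separation || !fit$converged)
    stop("propensity fit error: complete or quasi-complete separation ",
         "(logistic fit did not stabilize)")
  p <- matrix(NA_real_, nrow(panel$at_risk), ncol(panel$at_risk))
  p[cbind(df$.row, df$.k)] <- pmin(pmax(fit$fitted.values, 1e-6), 1 - 1e-6)
  structure(list(p = p, method = "logistic", terms = terms, glm = fit,
                 trace = stats::deviance(fit), seed = NA_integer_),
            class = "snaftm_propensity")
}

.fit_propensity_rnn <- function(panel, terms, hidden, lr, epochs, patience,
                                val_frac, seed) {
  n <- length(panel$subject_id)
  at <- panel$at_risk
  x_list <- .net_inputs(panel, terms)
  set.seed(seed)
  val <- sort(sample.int(n, max(1L, floor(val_frac * n))))
  train <- setdiff(seq_len(n), val)
  Afill <- panel$A_fill

  ce_loss <- function(p, rows) {
    m <- at[rows, , drop = FALSE]
    pr <- p[rows, , drop = FALSE][m]
    aa <- Afill[rows, , drop = FALSE][m]
    -mean(aa * log(pr) + (1 - aa) * log(1 - pr))
  }

  params <- .rnn_init(ncol(x_list[[1L]]), hidden, seed)
  state <- .adam_init(params)
  best <- list(loss = Inf, params = params)
  wait <- 0L
  trace <- numeric(0)
  x_train <- lapply(x_list, function(m) m[train, , drop = FALSE])
  n_train_rec <- sum(at[train, ])
  for (ep in seq_len(epochs)) {
    fwd <- .rnn_forward(params, x_train)
    p_tr <- stats::plogis(fwd$z)
    # sigmoid cross-entropy shortcut: dL/dz = (p - a) / n over at-risk cells
    dZ <- (p_tr - Afill[train, , drop = FALSE]) / n_train_rec
    dZ[!at[train, , drop = FALSE]] <- 0
    grads <- .rnn_backward(params, x_train, fwd, dZ)
    upd <- .adam_step(params, grads, state, lr = lr)
    params <- upd$params
    state <- upd$state

    p_full <- stats::plogis(.rnn_forward(params, x_list)$z)
    p_full <- pmin(pmax(p_full, 1e-6), 1 - 1e-6)
    vloss <- ce_loss(p_full, val)
    if (!is.finite(vloss)) stop("training error: non-finite loss")
    trace <- c(trace, vloss)
    if (vloss < best$loss - 1e-7) {
      best <- list(loss = vloss, params = params)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  p <- stats::plogis(.rnn_forward(best$params, x_list)$z)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  p[!at] <- NA_real_
  structure(list(p = p, method = "recurrent", terms = terms,
                 params = best$params, trace = trace, seed = seed,
                 val_rows = val),
            class = "snaftm_propensity")
}

#' @export
print.snaftm_propensity <- function(x, ...) {
  cat("Propensity fit (", x$method, "): ",
      sum(!is.na(x$p)), " at-risk records, mean p-hat = ",
      sprintf("%.3f", mean(x$p, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Exposure-model residuals
#'
#' Elementwise residuals \eqn{r_{ik} = A_{ik} - \hat p_{ik}} on the at-risk
#' records; `NA` elsewhere. For a logistic fit with intercept these satisfy
#' the score equations (orthogonality to each design column).
#'
#' @param object a `snaftm_propensity`.
#' @param panel the panel the fit was produced from.
#' @param ... unused.
#' @return Matrix of residuals (subjects by visits).
#' @export
residuals.snaftm_propensity <- function(object, panel, ...) {
  if (!identical(dim(object$p), dim(panel$A)))
    stop("alignment error: propensity fit does not match the panel")
  at <- panel$at_risk
  if (any(is.na(object$p[at])))
    stop("alignment error: missing propensity for an at-risk record")
  r <- panel$A - object$p
  r[!at] <- NA_real_
  r
}

#' Draw null exposure copies from the fitted mechanism
#'
#' Generates `M` independent Bernoulli(\eqn{\hat p_{ik}}) exposure paths on
#' the at-risk records. These preserve the dependence of exposure on measured
#' history but are drawn without reference to any outcome, providing the
#' null-hypothesis samples used by the mimic estimator.
#'
#' @param fit a `snaftm_propensity`.
#' @param M number of copies (>= 1).
#' @param seed integer seed; fixed seed gives identical draws.
#' @return A subjects-by-visits-by-M array of 0/1 draws (`NA` off-risk).
#' @export
draw_null_exposures <- function(fit, M, seed = 1) {
  stopifnot(inherits(fit, "snaftm_propensity"))
  if (M < 1) stop("parameter error: M must be >= 1")
  p <- fit$p
  set.seed(seed)
  n <- nrow(p); K1 <- ncol(p)
  out <- array(NA_real_, c(n, K1, M))
  ok <- !is.na(p)
  for (m in seq_len(M)) {
    draw <- matrix(NA_real_, n, K1)
    draw[ok] <- as.numeric(stats::runif(sum(ok)) < p[ok])
    out[, , m] <- draw
  }
  out
}
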
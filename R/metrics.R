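#' Bias summary of an estimate against the generating truth
#'
#' Aligns the estimate with the stored true per-visit effects on the at-risk
#' subject-visit records and reports three statistics: the mean bias
#' (mean of \eqn{\hat\psi_{ik} - \psi^*_{ik}}), its absolute value, and the
#' mean absolute bias (mean of \eqn{|\hat\psi_{ik} - \psi^*_{ik}|}). A scalar
#' estimate (g-estimation) is broadcast over the records; an individualized
#' matrix (network estimators) is aligned cellwise and `NA` cells (e.g.
#' subjects outside the test split) are dropped.
#'
#' @param psi_hat scalar, length-1 vector, or subjects-by-visits matrix.
#' @param psi_true subjects-by-visits matrix of generating effects.
#' @param at_risk logical subjects-by-visits at-risk matrix (or a
#'   `snaftm_panel` from which it is taken).
#' @return A list with `mean_bias`, `abs_bias`, `mean_abs_bias`, and the
#'   record count `n`.
#' @export
bias_summary <- function(psi_hat, psi_true, at_risk) {
  if (inherits(at_risk, "snaftm_panel")) at_risk <- at_risk$at_risk
  stopifnot(is.matrix(psi_true), identical(dim(psi_true), dim(at_risk)))
  if (!is.matrix(psi_hat)) {
    if (length(psi_hat) != 1L)
      stop("alignment error: psi_hat must be a scalar or a matrix")
    psi_hat <- matrix(psi_hat, nrow(psi_true), ncol(psi_true))
  }
  stopifnot(identical(dim(psi_hat), dim(psi_true)))
  keep <- at_risk & !is.na(psi_hat) & !is.na(psi_true)
  if (!any(keep)) stop("alignment error: no overlapping at-risk records")
  d <- psi_hat[keep] - psi_true[keep]
  mb <- mean(d)
  list(mean_bias = mb, abs_bias = abs(mb), mean_abs_bias = mean(abs(d)),
       n = sum(keep))
}

#' Acceleration factor implied by a causal parameter
#'
#' Converts the magnitude of the blip parameter into the multiplicative
#' compression of event-free time under exposure, \eqn{e^{-|\psi|}}. A value
#' of 0 gives factor 1 (no effect).
#'
#' @param psi finite causal parameter (either sign convention).
#' @return The compression factor in (0, 1].
#' @export
acceleration_factor <- function(psi) {
  stopifnot(all(is.finite(psi)))
  exp(-abs(psi))
}

#' Weibull rate ratio implied by a causal parameter
#'
#' If the counterfactual unexposed survival time follows a Weibull
#' distribution with the given shape, the acceleration of time by
#' \eqn{e^{\psi}} corresponds to an event rate ratio \eqn{e^{shape \cdot \psi}}.
#'
#' @param psi causal parameter magnitude.
#' @param shape Weibull shape parameter, positive.
#' @return The rate ratio.
#' @export
weibull_rate_ratio <- function(psi, shape) {
  if (any(shape <= 0)) stop("parameter error: shape must be positive")
  exp(shape * psi)
}

#' Replicated simulation benchmark of the estimators
#'
#' For each replicate, simulates a dataset from the scenario config (seed
#' `base seed + replicate`), fits every requested method, and summarizes the
#' bias of the estimate against the stored truth. A method failure inside a
#' replicate is recorded and the benchmark continues. The output is a pure
#' function of the config and seeds.
#'
#' @param config a [scenario_config()]; its `seed` is replaced per replicate.
#' @param methods character vector among
#'   `c("gest1d", "gest2d", "ge_score", "ge_mimic")`.
#' @param reps number of replicates.
#' @param seed base seed.
#' @param method_args named list of per-method argument lists passed on to
#'   [snaftm()] (e.g. `list(gest2d = list(modifier = "L"))`).
#' @return An object of class `snaftm_benchmark`: a list with the
#'   per-replicate `results` data frame (estimate, bias statistics, error
#'   messages) and the `aggregate` per-method summary.
#' @export
run_benchmark <- function(config, methods = c("gest1d"), reps = 10,
                          seed = 1, method_args = list()) {
  stopifnot(inherits(config, "scenario_config"), reps >= 1)
  ok_methods <- c("gest1d", "gest2d", "ge_score", "ge_mimic")
  stopifnot(all(methods %in% ok_methods))
  rows <- list()
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    panel <- simulate_scenario(cfg)
    truth <- attr(panel, "truth")
    pfit <- tryCatch(fit_propensity(panel), error = function(e) e)
    for (m in methods) {
      row <- data.frame(replicate = r, seed = cfg$seed, method = m,
                        estimate = NA_real_, mean_bias = NA_real_,
                        abs_bias = NA_real_, mean_abs_bias = NA_real_,
                        error = NA_character_, stringsAsFactors = FALSE)
      res <- if (inherits(pfit, "error")) pfit else tryCatch({
        args <- c(list(panel = panel, method = m, propensity = pfit),
                  if (m %in% c("ge_score", "ge_mimic")) list(seed = cfg$seed),
                  method_args[[m]])
        do.call(snaftm, args)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        est <- if (!is.null(res$psi)) {
          # network methods are scored on their test-split predictions
          m_est <- res$psi
          if (!is.null(res$split))
            m_est[setdiff(seq_len(nrow(m_est)), res$split$test), ] <- NA_real_
          m_est
        } else unname(res$estimate[1L])
        if (res$method == "gest2d") {
          mod <- .modifier_matrix(panel, res$config$modifier)
          est <- res$estimate[1L] + res$estimate[2L] * mod
        }
        bs <- bias_summary(est, truth$psi, panel)
        row$estimate <- unname(res$estimate[1L])
        row$mean_bias <- bs$mean_bias
        row$abs_bias <- bs$abs_bias
        row$mean_abs_bias <- bs$mean_abs_bias
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(results, results$method), function(d) {
    data.frame(method = d$method[1L],
               n_ok = sum(!is.na(d$mean_bias)),
               mean_estimate = mean(d$estimate, na.rm = TRUE),
               mean_bias = mean(d$mean_bias, na.rm = TRUE),
               median_abs_bias = stats::median(d$abs_bias, na.rm = TRUE),
               median_mean_abs_bias = stats::median(d$mean_abs_bias, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(results = results, aggregate = agg, config = config,
                 seed = seed),
            class = "snaftm_benchmark")
}

#' @export
print.snaftm_benchmark <- function(x, ...) {
  cat("SNAFTM benchmark: scenario", x$config$scenario,
      "(", x$config$direction, "),",
      max(x$results$replicate), "replicates\n")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}
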
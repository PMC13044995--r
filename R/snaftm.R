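#' Fit a structural nested accelerated failure time model
#'
#' Front-end for all estimators of the per-visit causal acceleration
#' parameter \eqn{\psi} of a binary time-varying exposure on a time-to-event
#' outcome. The reporting convention throughout the package is the usual AFT
#' one: \eqn{\psi > 0} means exposure extends event-free time by a factor
#' \eqn{e^{\psi}} per exposed interval (internally the blip engine works with
#' \eqn{\phi = -\psi}).
#'
#' Methods:
#' \describe{
#'   \item{`gest1d`}{Grid-search g-estimation of a constant \eqn{\psi}. For
#'     each grid value the counterfactual untreated outcomes are recomputed,
#'     artificially censored, and a score test of their conditional
#'     independence from the exposure (given history) is evaluated; the
#'     estimate minimizes the test statistic and the 95\% confidence set is
#'     obtained by test inversion.}
#'   \item{`gest2d`}{As `gest1d` for
#'     \eqn{\psi_{ik} = \psi_1 + \psi_2\,\mathrm{modifier}_{ik}} on a 2-d
#'     grid.}
#'   \item{`ge_score`}{Recurrent-network estimator producing individualized
#'     \eqn{\hat\psi_{ik}}, trained by the correlation (score) loss against
#'     exposure-model residuals; see [ge_score_loss()].}
#'   \item{`ge_mimic`}{Same network trained by matching observed dependence
#'     statistics to their null distribution under redrawn exposures; see
#'     [ge_mimic_loss()].}
#' }
#'
#' @param panel a `snaftm_panel` (see [panel_data()]).
#' @param method one of `"gest1d"`, `"gest2d"`, `"ge_score"`, `"ge_mimic"`.
#' @param propensity optional pre-fitted `snaftm_propensity`; by default a
#'   pooled logistic exposure model with the standard design
#'   (current covariates, previous exposure, visit effects) is fitted.
#' @param ... method-specific settings. Grid methods: `grid` (bounds,
#'   default `c(-1, 1)`), `step` (default 0.01 for 1-d, 0.05 for 2-d),
#'   `g_fun` (`"delta_star"`, `"delta"` or `"X"`), `modifier` (2-d only),
#'   `level`. Network methods: `hidden` (16), `psi_max` (2), `gamma1` (100),
#'   `gamma2` (10), `lr`, `epochs` (200), `patience` (20), `inputs`,
#'   `split` (`c(0.7, 0.2, 0.1)`), `seed`, and `M` (null copies, `ge_mimic`
#'   only, default 100).
#' @return An object of class `snaftm` (subclassed by method) with the point
#'   `estimate` (scalar \eqn{\hat\psi}, pair \eqn{(\hat\psi_1, \hat\psi_2)},
#'   or the test-split mean of the individualized \eqn{\hat\psi_{ik}}), a
#'   test-inversion confidence interval (grid methods) or prediction `range`
#'   (network methods), the individualized matrix `psi` where applicable, the
#'   loss/statistic `trace`, and the configuration snapshot.
#' @examples
#' cfg <- scenario_config("I", "beneficial", n = 200, seed = 7,
#'                        censor_rate = 0.1)
#' panel <- simulate_scenario(cfg)
#' fit <- snaftm(panel, method = "gest1d", step = 0.05)
#' coef(fit)
#' confint(fit)
#' @export
snaftm <- function(panel,
                   method = c("gest1d", "gest2d", "ge_score", "ge_mimic"),
                   propensity = NULL, ...) {
  stopifnot(inherits(panel, "snaftm_panel"))
  method <- match.arg(method)
  if (is.null(propensity)) propensity <- fit_propensity(panel)
  stopifnot(inherits(propensity, "snaftm_propensity"))
  out <- switch(method,
    gest1d = .fit_gest1d(panel, propensity, ...),
    gest2d = .fit_gest2d(panel, propensity, ...),
    ge_score = .fit_ge_score(panel, propensity, ...),
    ge_mimic = .fit_ge_mimic(panel, propensity, ...)
  )
  out$propensity_method <- propensity$method
  out$call <- match.call()
  out
}

# common constructor for fit results
.new_snaftm <- function(method, estimate, conf_int = NULL, trace, config,
                        panel, range = NULL, per_visit = NULL, psi = NULL,
                        split = NULL, params = NULL) {
  structure(
    list(method = method, estimate = estimate, conf_int = conf_int,
         range = range, per_visit = per_visit, psi = psi, split = split,
         trace = trace, config = config, params = params,
         n_subjects = length(panel$subject_id),
         n_records = sum(panel$V + 1L),
         schedule = panel$schedule),
    class = c(paste0("snaftm_", method), "snaftm")
  )
}

#' @export
print.snaftm <- function(x, ...) {
  cat("SNAFTM fit (", x$method, "), ", x$n_subjects, " subjects, ",
      x$n_records, " person-visit records\n", sep = "")
  if (x$method %in% c("gest1d", "gest2d")) {
    est <- x$estimate
    cat("psi estimate:", paste(sprintf("%.4f", est), collapse = ", "), "\n")
    if (is.matrix(x$conf_int)) {
      cat(sprintf("95%% confidence set (box): psi1 [%.3f, %.3f], psi2 [%.3f, %.3f]\n",
                  x$conf_int[1, 1], x$conf_int[1, 2],
                  x$conf_int[2, 1], x$conf_int[2, 2]))
    } else {
      cat(sprintf("95%% confidence interval: [%.3f, %.3f]\n",
                  x$conf_int[1], x$conf_int[2]))
    }
  } else {
    cat(sprintf("mean individualized psi (test split): %.4f  range [%.4f, %.4f]\n",
                x$estimate, x$range[1], x$range[2]))
  }
  invisible(x)
}

#' @export
summary.snaftm <- function(object, ...) {
  out <- list(method = object$method, estimate = object$estimate,
              conf_int = object$conf_int, range = object$range,
              per_visit = object$per_visit,
              n_subjects = object$n_subjects, n_records = object$n_records,
              config = object$config)
  class(out) <- "summary.snaftm"
  out
}

#' @export
print.summary.snaftm <- function(x, ...) {
  cat("Method:", x$method, "\n")
  cat("Estimate:", paste(sprintf("%.4f", x$estimate), collapse = ", "), "\n")
  if (!is.null(x$conf_int) && !is.matrix(x$conf_int))
    cat(sprintf("95%% CI: [%.4f, %.4f]\n", x$conf_int[1], x$conf_int[2]))
  if (!is.null(x$range))
    cat(sprintf("Prediction range: [%.4f, %.4f]\n", x$range[1], x$range[2]))
  if (!is.null(x$per_visit)) {
    cat("Per-visit summaries (test split):\n")
    print(x$per_visit, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.snaftm <- function(object, ...) object$estimate

#' @export
confint.snaftm <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$conf_int))
    stop("confidence intervals are only available for grid-search g-estimation; ",
         "network estimators report a prediction range (see $range)")
  if (!missing(level) && !isTRUE(all.equal(level, object$config$level)))
    stop("refit with the requested level; stored confidence set is at ",
         object$config$level)
  object$conf_int
}
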
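#' Blip transform of a single interval
#'
#' Removes the effect of an exposure blip on the interval \eqn{(t_k, y]}:
#' the transformed time is \eqn{t_k + (y - t_k)\exp(\phi a)}. Here `phi` is
#' the internal removal-inflation parameter; under the package's reporting
#' convention (positive \eqn{\psi} extends event-free time) it equals
#' \eqn{\phi = -\psi}. The transform is the identity when `a = 0` or
#' `phi = 0`.
#'
#' @param y time strictly greater than `t_k`.
#' @param t_k visit time opening the interval.
#' @param phi real blip parameter (internal sign convention).
#' @param a binary exposure on the interval.
#' @return Transformed time, vectorized over the inputs.
#' @export
apply_blip <- function(y, t_k, phi, a) {
  if (any(y <= t_k)) stop("domain error: y must exceed t_k")
  t_k + (y - t_k) * exp(phi * a)
}

#' Counterfactual unexposed survival time from visit k onward
#'
#' Accumulates the per-interval blip transforms of the observed follow-up
#' from visit \eqn{k} to the subject's last at-risk visit:
#' \deqn{H(\psi, k) = t_k + \sum_{u=k}^{V} (\min(T, t_{u+1}) - t_u)\,
#'   e^{\phi_u a_u},}
#' with \eqn{t_{K+1} = \tau}. This is the exact discretization of the
#' continuous-time transform when exposure jumps only at visit times.
#'
#' @param T_obs observed time of the subject (event or censoring).
#' @param a exposure vector over visits `0..K` (entries beyond the last
#'   at-risk visit are ignored).
#' @param phi blip parameters over visits `0..K` (internal convention,
#'   `phi = -psi`); a scalar is recycled.
#' @param schedule a [visit_schedule()].
#' @param k 0-based visit at which the counterfactual clock starts.
#' @return The counterfactual time \eqn{H(\psi, k)}.
#' @export
counterfactual_time <- function(T_obs, a, phi, schedule, k = 0) {
  stopifnot(inherits(schedule, "visit_schedule"))
  tk <- schedule$visit_times
  K <- schedule$K
  if (k < 0 || k > K) stop("visit index out of range")
  if (T_obs <= tk[k + 1L]) stop("domain error: subject not at risk at visit k")
  a <- rep_len(a, K + 1L)
  phi <- rep_len(phi, K + 1L)
  upper <- c(tk[-1L], schedule$end_of_study)
  u <- (k + 1L):(K + 1L)
  d <- pmax(0, pmin(T_obs, upper[u]) - tk[u])
  tk[k + 1L] + sum(d * exp(phi[u] * a[u]))
}

#' Minimal potential follow-up at visit k
#'
#' The earliest transformed administrative censoring time over a batch:
#' each subject's full follow-up grid \eqn{t_k, \dots, \tau} is transformed
#' with the same blip factors applied to the event time (exposure carried
#' forward beyond the last observed visit), and the batch minimum is taken.
#' Recensoring the counterfactual times at this value keeps censoring
#' non-informative on the transformed scale.
#'
#' @param panel a `snaftm_panel`.
#' @param phi matrix of blip parameters (subjects by visits, internal
#'   convention) or a scalar.
#' @param k 0-based visit index.
#' @param subset optional integer vector of subject rows forming the batch
#'   (default: all subjects at risk at `k`).
#' @return The scalar batch minimum \eqn{C(\psi, k)}.
#' @export
minimal_potential_followup <- function(panel, phi, k, subset = NULL) {
  stopifnot(inherits(panel, "snaftm_panel"))
  K <- panel$schedule$K
  if (k < 0 || k > K) stop("visit index out of range")
  phi_mat <- .as_phi_matrix(panel, phi)
  cand <- .cf_Ccand(panel, phi_mat)
  rows <- if (is.null(subset)) which(panel$at_risk[, k + 1L]) else
    intersect(subset, which(panel$at_risk[, k + 1L]))
  if (length(rows) == 0L) stop("domain error: empty batch at visit ", k)
  min(cand[rows, k + 1L])
}

#' Artificial censoring of a counterfactual time
#'
#' Recensors the counterfactual time `H` at the minimal potential follow-up
#' `C`: \eqn{X = \min(H, C)}, \eqn{\Delta = 1\{H < C\}}, and the smoothed
#' indicator \eqn{\Delta^* = 1 - X/C} when \eqn{X < C} and 0 otherwise.
#' \eqn{\Delta^*} lies in \eqn{[0,1]} and is positive exactly when
#' \eqn{\Delta = 1}, which makes it usable inside gradient-based losses.
#'
#' @param H counterfactual time(s), positive.
#' @param C minimal potential follow-up, positive (recycled).
#' @return A data frame with columns `X`, `delta`, `delta_star`.
#' @export
artificial_censor <- function(H, C) {
  if (any(H <= 0) || any(C <= 0))
    stop("domain error: H and C must be positive")
  X <- pmin(H, C)
  delta <- as.integer(H < C)
  delta_star <- ifelse(delta == 1L, 1 - X / C, 0)
  data.frame(X = X, delta = delta, delta_star = delta_star)
}

#' Invert the blip transform (rank-preserving outcome generation)
#'
#' Given an untreated event time `T0`, per-visit causal parameters `psi`
#' (reporting convention: positive extends event-free time) and an exposure
#' path, returns the unique observed time `Y` whose counterfactual transform
#' from visit 0 equals `T0`. The final interval \eqn{(t_K, \infty)} is
#' unbounded; administrative censoring is the caller's responsibility.
#'
#' @param T0 positive untreated time(s); vectorized over subjects.
#' @param psi per-visit causal parameters: a vector over visits `0..K` or a
#'   matrix (subjects by visits).
#' @param a exposure path, same shape as `psi`.
#' @param schedule a [visit_schedule()].
#' @return Observed time(s) `Y`.
#' @export
invert_blip_transform <- function(T0, psi, a, schedule) {
  stopifnot(inherits(schedule, "visit_schedule"))
  if (any(T0 <= 0)) stop("domain error: T0 must be positive")
  n <- length(T0)
  K <- schedule$K
  tk <- schedule$visit_times
  as_mat <- function(x) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == n, ncol(x) == K + 1L)
      x
    } else matrix(rep_len(x, K + 1L), n, K + 1L, byrow = TRUE)
  }
  psi <- as_mat(psi)
  a <- as_mat(a)
  f <- exp(-psi * a)                     # transformed-time rate per interval
  d <- diff(tk)                          # interior interval lengths
  caps <- cbind(if (K > 0) sweep(f[, seq_len(K), drop = FALSE], 2, d, "*"),
                rep(Inf, n))             # last interval open-ended
  Y <- numeric(n)
  rem <- T0
  done <- rep(FALSE, n)
  for (u in seq_len(K + 1L)) {
    hit <- !done & (rem <= caps[, u])
    Y[hit] <- tk[u] + rem[hit] / f[hit, u]
    done <- done | hit
    rem <- rem - caps[, u]
  }
  Y
}

# --- internal vectorized engine ---------------------------------------------

# coerce scalar / matrix phi to an n x (K+1) matrix
.as_phi_matrix <- function(panel, phi) {
  n <- length(panel$subject_id)
  K1 <- panel$schedule$K + 1L
  if (is.matrix(phi)) {
    stopifnot(nrow(phi) == n, ncol(phi) == K1)
    phi
  } else {
    matrix(rep_len(phi, K1), n, K1, byrow = TRUE)
  }
}

# observed interval durations: d[i,u] = max(0, min(T_i, t_{u+1}) - t_u)
.obs_durations <- function(panel) {
  tk <- panel$schedule$visit_times
  upper <- c(tk[-1L], panel$schedule$end_of_study)
  d <- outer(panel$time, upper, pmin) -
    matrix(tk, length(panel$time), length(tk), byrow = TRUE)
  d[d < 0] <- 0
  d
}

# row-wise reverse cumulative sum over visit columns
.revcumsum <- function(m) {
  if (ncol(m) == 1L) return(m)
  m[, rev(seq_len(ncol(m))), drop = FALSE] |>
    apply(1L, cumsum) |>
    t() |>
    (\(x) x[, rev(seq_len(ncol(x))), drop = FALSE])()
}

# H[i, k+1] = t_k + sum_{u >= k} d_obs[i,u] exp(phi[i,u] A[i,u]);
# valid on at-risk cells. Also returns E (per-interval transformed lengths).
.cf_H <- function(panel, phi_mat) {
  A <- panel$A_fill
  E <- .obs_durations(panel) * exp(phi_mat * A)
  H <- sweep(.revcumsum(E), 2, panel$schedule$visit_times, "+")
  list(H = H, E = E)
}

# candidate minimal potential follow-up per subject and visit:
# Ccand[i, k+1] = t_k + sum_{u=k}^{K} (t_{u+1} - t_u) exp(phi[i,u] A_fill[i,u])
.cf_Ccand <- function(panel, phi_mat) {
  dfull <- .full_durations(panel$schedule)
  Ef <- sweep(exp(phi_mat * panel$A_fill), 2, dfull, "*")
  sweep(.revcumsum(Ef), 2, panel$schedule$visit_times, "+")
}

# counterfactual set for one visit k over a batch of subject rows;
# C is the batch minimum of the candidate follow-ups
.cf_visit <- function(panel, phi_mat, k, rows, H_all = NULL, Ccand = NULL) {
  if (is.null(H_all)) H_all <- .cf_H(panel, phi_mat)$H
  if (is.null(Ccand)) Ccand <- .cf_Ccand(panel, phi_mat)
  rows <- rows[panel$at_risk[rows, k + 1L]]
  if (length(rows) == 0L) stop("domain error: empty batch at visit ", k)
  H <- H_all[rows, k + 1L]
  C <- min(Ccand[rows, k + 1L])
  X <- pmin(H, C)
  delta <- as.integer(H < C)
  list(rows = rows, H = H, C = C, X = X, delta = delta,
       delta_star = ifelse(delta == 1L, 1 - X / C, 0))
}

#' Counterfactual set for a panel at every visit
#'
#' Computes, for each visit \eqn{k} and each subject at risk there, the
#' counterfactual unexposed time `H`, the batch minimal potential follow-up
#' `C`, the artificially censored time `X`, the event indicator `delta` and
#' its smoothed version `delta_star`. Mainly a debugging/export surface; the
#' estimators use the same engine internally.
#'
#' @param panel a `snaftm_panel`.
#' @param psi causal parameters in the reporting convention (scalar or
#'   subjects-by-visits matrix); internally \eqn{\phi = -\psi}.
#' @return A data frame with columns `subject_id`, `visit`, `H`, `C`, `X`,
#'   `delta`, `delta_star`.
#' @export
counterfactual_set <- function(panel, psi) {
  stopifnot(inherits(panel, "snaftm_panel"))
  phi_mat <- -.as_phi_matrix(panel, psi)
  H_all <- .cf_H(panel, phi_mat)$H
  Ccand <- .cf_Ccand(panel, phi_mat)
  K <- panel$schedule$K
  out <- lapply(0:K, function(k) {
    cf <- .cf_visit(panel, phi_mat, k, seq_along(panel$subject_id),
                    H_all = H_all, Ccand = Ccand)
    data.frame(subject_id = panel$subject_id[cf$rows], visit = k,
               H = cf$H, C = cf$C, X = cf$X, delta = cf$delta,
               delta_star = cf$delta_star, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
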
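#' Long-format person-visit panel
#'
#' Validates and packs a long-format person-visit data frame into the panel
#' container used by all estimators. One row per subject-visit; reserved
#' columns are `subject_id`, `visit` (0-based index), `time` (visit time,
#' optional on input), `A` (binary exposure), `T` (observed event or censoring
#' time), `event` (1 = event observed). Every remaining column is treated as a
#' covariate; baseline covariates are simply covariates repeated on each row.
#'
#' Each subject must contribute exactly the rows for visits
#' \eqn{k = 0, \dots, V} where \eqn{V = \max\{k : t_k < T\}} is the last visit
#' at which the subject is still at risk. Rows carried for visits after
#' \eqn{V} are dropped with a warning (real extracts often contain them);
#' missing rows before \eqn{V} are an error.
#'
#' @param df long-format data frame (see Details).
#' @param schedule a [visit_schedule()].
#' @return An object of class `snaftm_panel`: a list with the schedule,
#'   per-subject vectors (`subject_id`, `time` = observed T, `event`, `V`),
#'   the exposure matrix `A` (subjects by visits, `NA` after V), a named list
#'   `covariates` of matrices of the same shape, the at-risk indicator matrix
#'   `at_risk`, and carried-forward copies `A_fill` / `cov_fill` used by the
#'   artificial-censoring engine.
#' @seealso [read_panel()], [write_panel()], [at_risk_mask()]
#' @export
panel_data <- function(df, schedule) {
  stopifnot(inherits(schedule, "visit_schedule"))
  df <- as.data.frame(df)
  required <- c("subject_id", "visit", "A", "T", "event")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("panel format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  reserved <- c(required, "time")
  cov_names <- setdiff(names(df), reserved)
  if (length(cov_names) == 0L)
    stop("panel format error: at least one covariate column is required")

  tk <- schedule$visit_times
  K <- schedule$K
  tau <- schedule$end_of_study

  df$subject_id <- as.character(df$subject_id)
  df$visit <- as.integer(df$visit)
  ids <- unique(df$subject_id)
  n <- length(ids)
  ord <- order(match(df$subject_id, ids), df$visit)
  if (any(ord != seq_len(nrow(df)))) {
    # visits must be recorded in increasing order within subject
    by_subj <- split(df$visit, df$subject_id)
    if (any(vapply(by_subj, function(v) any(diff(v) <= 0), logical(1L))))
      stop("panel validation error: non-monotone or duplicated visits within subject")
    df <- df[ord, , drop = FALSE]
  }

  first_rows <- match(ids, df$subject_id)
  T_i <- df$T[first_rows]
  event_i <- as.integer(df$event[first_rows])
  if (any(tapply(df$T, df$subject_id, function(x) max(x) - min(x)) > 1e-9))
    stop("panel validation error: T must be constant within subject")
  if (any(!is.finite(T_i)) || any(T_i <= 0))
    stop("panel validation error: observed time T must be positive")
  if (any(T_i > tau + 1e-9))
    stop("panel validation error: observed time T exceeds end of study")
  if (!all(event_i %in% c(0L, 1L)))
    stop("panel validation error: event must be 0/1")
  if (!all(df$A %in% c(0, 1)))
    stop("panel validation error: exposure A must be 0/1")
  if (any(df$visit < 0L) || any(df$visit > K))
    stop("panel validation error: visit index out of schedule range")

  # V_i = max{k: t_k < T_i}; t_0 = 0 < T guarantees V >= 0
  V_i <- vapply(T_i, function(tt) max(which(tk < tt)) - 1L, integer(1L))

  keep <- df$visit <= V_i[match(df$subject_id, ids)]
  if (any(!keep)) {
    warning(sum(!keep), " row(s) after the subject's last at-risk visit dropped")
    df <- df[keep, , drop = FALSE]
  }

  if ("time" %in% names(df)) {
    if (any(abs(df$time - tk[df$visit + 1L]) > 1e-6))
      stop("panel validation error: 'time' column disagrees with the schedule")
  }

  # every subject must have rows 0..V
  cnt <- tabulate(match(df$subject_id, ids), nbins = n)
  if (any(cnt != V_i + 1L))
    stop("panel validation error: subjects must contribute exactly one row ",
         "per at-risk visit 0..V")

  row_i <- match(df$subject_id, ids)
  row_k <- df$visit + 1L
  idx <- cbind(row_i, row_k)

  A <- matrix(NA_real_, n, K + 1L)
  A[idx] <- as.numeric(df$A)
  covariates <- lapply(cov_names, function(cn) {
    m <- matrix(NA_real_, n, K + 1L)
    m[idx] <- as.numeric(df[[cn]])
    m
  })
  names(covariates) <- cov_names

  at_risk <- outer(T_i, tk, ">")

  carry <- function(m) {
    for (k in seq_len(K)) {
      miss <- is.na(m[, k + 1L])
      m[miss, k + 1L] <- m[miss, k]
    }
    m
  }

  structure(
    list(schedule = schedule,
         subject_id = ids,
         time = T_i,
         event = event_i,
         V = V_i,
         A = A,
         covariates = covariates,
         at_risk = at_risk,
         A_fill = carry(A),
         cov_fill = lapply(covariates, carry)),
    class = "snaftm_panel"
  )
}

#' Number of subjects in a panel
#' @param panel a `snaftm_panel`.
#' @return Integer subject count.
#' @export
n_subjects <- function(panel) length(panel$subject_id)

#' At-risk indicator at a visit
#'
#' A subject is at risk at visit \eqn{k} when the observed time exceeds the
#' visit time, \eqn{T_i > t_k}; equivalently \eqn{k \le V_i}. The indicator is
#' monotone non-increasing in \eqn{k} for every subject.
#'
#' @param panel a `snaftm_panel`.
#' @param k 0-based visit index.
#' @return Integer 0/1 vector over subjects.
#' @export
at_risk_mask <- function(panel, k) {
  K <- panel$schedule$K
  if (length(k) != 1L || is.na(k) || k < 0 || k > K)
    stop("visit index out of range [0, ", K, "]")
  as.integer(panel$at_risk[, k + 1L])
}

#' Write a panel to long-format CSV
#'
#' Emits one row per subject-visit (visits \eqn{0..V_i} only) with stable
#' column order `subject_id, visit, time, A, T, event`, then the covariates,
#' at full double precision. `read_panel(write_panel(x))` reproduces `x`.
#'
#' @param panel a `snaftm_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  for (cn in names(df))            # round-trip-exact doubles
    if (is.double(df[[cn]])) df[[cn]] <- sprintf("%.17g", df[[cn]])
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write panel to ", path)
  invisible(path)
}

#' @export
as.data.frame.snaftm_panel <- function(x, ...) {
  tk <- x$schedule$visit_times
  rows <- which(!is.na(t(x$A)))        # column-major over visits within subject
  kk <- (rows - 1L) %% ncol(x$A)       # 0-based visit
  ii <- (rows - 1L) %/% ncol(x$A) + 1L # subject row
  df <- data.frame(
    subject_id = x$subject_id[ii],
    visit = kk,
    time = tk[kk + 1L],
    A = x$A[cbind(ii, kk + 1L)],
    T = x$time[ii],
    event = x$event[ii],
    stringsAsFactors = FALSE
  )
  for (cn in names(x$covariates))
    df[[cn]] <- x$covariates[[cn]][cbind(ii, kk + 1L)]
  df
}

#' Read a long-format panel CSV
#'
#' @param path CSV path with the column layout described in [panel_data()].
#' @param schedule a [visit_schedule()].
#' @return A `snaftm_panel`.
#' @export
read_panel <- function(path, schedule) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  panel_data(df, schedule)
}

#' @export
print.snaftm_panel <- function(x, ...) {
  cat("SNAFTM panel:", n_subjects(x), "subjects,",
      sum(x$V + 1L), "person-visit records\n")
  print(x$schedule)
  cat("Covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  cat(sprintf("Events: %d (%.1f%%); exposure prevalence %.1f%%\n",
              sum(x$event), 100 * mean(x$event),
              100 * mean(x$A, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.snaftm_panel <- function(object, ...) {
  K <- object$schedule$K
  at_risk_n <- colSums(object$at_risk)
  exp_n <- colSums(object$A == 1, na.rm = TRUE)
  out <- data.frame(
    visit = 0:K,
    time = object$schedule$visit_times,
    at_risk = at_risk_n,
    exposed = exp_n,
    exposed_frac = ifelse(at_risk_n > 0, exp_n / at_risk_n, NA_real_)
  )
  class(out) <- c("summary.snaftm_panel", "data.frame")
  out
}
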
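#' Common visit schedule
#'
#' Defines the discrete visit grid \eqn{t_0 < t_1 < \dots < t_K} (in years)
#' shared by all subjects, together with the administrative end-of-study time
#' \eqn{\tau > t_K}. All subjects enter at \eqn{t_0 = 0}; staggered entry is
#' not supported.
#'
#' @param visit_times numeric vector of strictly increasing visit times,
#'   starting at 0.
#' @param end_of_study administrative censoring time \eqn{\tau}, strictly
#'   greater than the last visit time.
#' @return An object of class `visit_schedule` with elements `visit_times`,
#'   `end_of_study`, and `K` (the largest 0-based visit index).
#' @examples
#' visit_schedule(c(0, 2, 4), 6)
#' @export
visit_schedule <- function(visit_times, end_of_study) {
  visit_times <- as.numeric(visit_times)
  end_of_study <- as.numeric(end_of_study)
  if (length(visit_times) < 1L || anyNA(visit_times))
    stop("visit_times must be a non-empty numeric vector without NAs")
  if (visit_times[1L] != 0)
    stop("visit_times must start at t_0 = 0")
  if (any(diff(visit_times) <= 0))
    stop("visit_times must be strictly increasing")
  if (length(end_of_study) != 1L || is.na(end_of_study) ||
      end_of_study <= visit_times[length(visit_times)])
    stop("end_of_study must be a single time greater than the last visit time")
  structure(
    list(visit_times = visit_times,
         end_of_study = end_of_study,
         K = length(visit_times) - 1L),
    class = "visit_schedule"
  )
}

#' @export
print.visit_schedule <- function(x, ...) {
  cat("Visit schedule: t =", paste(x$visit_times, collapse = ", "),
      " (K =", x$K, "), end of study tau =", x$end_of_study, "\n")
  invisible(x)
}

#' Read a visit schedule from a YAML or JSON config file
#'
#' The file must contain fields `visit_times` and `end_of_study`. The format
#' is chosen by file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path path to the config file.
#' @return A [visit_schedule()].
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  if (is.null(cfg$visit_times) || is.null(cfg$end_of_study))
    stop("schedule config must contain 'visit_times' and 'end_of_study'")
  visit_schedule(cfg$visit_times, cfg$end_of_study)
}

# interval durations (t_{u+1} - t_u) on the full grid, with t_{K+1} = tau
.full_durations <- function(schedule) {
  diff(c(schedule$visit_times, schedule$end_of_study))
}
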
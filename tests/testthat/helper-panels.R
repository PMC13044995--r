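# small deterministic fixtures built in code

sched3 <- function() visit_schedule(c(0, 2, 4), 6)

# long-format frame for a set of subjects; x is a list of lists with fields
# T, event, A (vector over visits 0..V) and optionally L
make_long <- function(subjects, schedule = sched3()) {
  tk <- schedule$visit_times
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    V <- max(which(tk < s$T)) - 1L
    k <- 0:V
    data.frame(subject_id = sprintf("P%02d", i), visit = k, time = tk[k + 1L],
               A = s$A[k + 1L], T = s$T, event = s$event,
               L = if (is.null(s$L)) rep(0.5, V + 1L) else s$L[k + 1L])
  })
  do.call(rbind, rows)
}

make_panel <- function(subjects, schedule = sched3()) {
  panel_data(make_long(subjects, schedule), schedule)
}

# propensity object with prescribed probabilities (for controlled scores)
manual_propensity <- function(panel, p) {
  pm <- if (is.matrix(p)) p else
    matrix(p, nrow(panel$at_risk), ncol(panel$at_risk))
  pm[!panel$at_risk] <- NA_real_
  structure(list(p = pm, method = "manual", terms = character(0),
                 trace = numeric(0), seed = NA_integer_),
            class = "snaftm_propensity")
}
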
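#' Simulate one dataset from a resolved scenario
#'
#' Generates a long-format counting-process data frame.  Clustered data have
#' one row per subject on `(0, stop]`; recurrent data have one row per event
#' episode, with disjoint ordered intervals in calendar time, plus a
#' terminal censored row for subjects still under observation at the
#' censoring time.  The frailty is drawn once per cluster (clustered
#' structures) or per subject (recurrent) and retained in the
#' `true_frailty` column for diagnostics.
#'
#' Clustered event times are drawn by exact inversion of the conditional
#' Weibull cumulative hazard
#' `Lambda(t | Z, x) = Z * gamma * alpha * exp(beta0 x) t^(alpha + beta1 x) / (alpha + beta1 x)`.
#' Recurrent events arise from a conditional intensity process of the same
#' form in calendar time, built from unit-exponential increments, with each
#' subject followed until their `group_size`-th event (the design's
#' events-per-subject scale) or the administrative censoring time,
#' whichever comes first.
#'
#' @param rs a [resolve_scenario()] object.
#' @param seed integer seed; required, so that every dataset is reproducible.
#' @return a `data.frame` with columns `cluster_id`, `subject_id`, `start`,
#'   `stop`, `status`, `x`, `true_frailty`.
#' @examples
#' rs <- resolve_scenario(scenario("clustered", 2, 100), censor = FALSE)
#' d <- simulate_dataset(rs, seed = 1)
#' head(d)
#' @export
simulate_dataset <- function(rs, seed) {
  if (!inherits(rs, "resolved_scenario"))
    stop_domain("'rs' must be a resolved_scenario")
  if (missing(seed) || is.null(seed))
    stop_domain("'seed' is required for reproducible simulation")
  set.seed(seed)
  if (rs$structure == "recurrent") .simulate_recurrent(rs) else .simulate_clustered(rs)
}

.simulate_clustered <- function(rs) {
  n_cl <- rs$total_size %/% rs$group_size
  n <- rs$total_size
  z_cl <- .draw_frailty(rs, n_cl)
  cluster <- rep(seq_len(n_cl), each = rs$group_size)
  x <- if (rs$structure == "clustered_common") {
    rep(stats::rbinom(n_cl, 1, rs$covariate_p), each = rs$group_size)
  } else {
    stats::rbinom(n, 1, rs$covariate_p)
  }
  z <- z_cl[cluster]
  cp <- .cond_pars(rs, z, x)
  t_ev <- (stats::rexp(n) / cp$K)^(1 / cp$a)
  stop <- pmin(t_ev, rs$censor_time)
  data.frame(cluster_id = cluster, subject_id = seq_len(n),
             start = 0, stop = stop,
             status = as.integer(t_ev <= rs$censor_time),
             x = x, true_frailty = z)
}

## calendar event times of the truncated recurrent process: each subject
## experiences exactly group_size events (the process stops at the last
## one), generated from unit-exponential increments of the conditional
## cumulative intensity; returns an n_subjects x j matrix
.recurrent_event_times <- function(rs, z, x) {
  j <- rs$group_size
  cp <- .cond_pars(rs, z, x)
  lam <- matrix(stats::rexp(length(z) * j), length(z), j)
  if (j > 1) for (k in 2:j) lam[, k] <- lam[, k - 1] + lam[, k]
  (lam / cp$K)^(1 / cp$a)
}

.simulate_recurrent <- function(rs) {
  n_s <- rs$total_size %/% rs$group_size
  j <- rs$group_size
  z <- .draw_frailty(rs, n_s)
  x <- stats::rbinom(n_s, 1, rs$covariate_p)
  tt <- .recurrent_event_times(rs, z, x)
  tc <- rs$censor_time
  n_ev <- rowSums(tt <= tc)
  ## a censored terminal row only when observation ends before the last event
  rows <- n_ev + as.integer(n_ev < j)
  subj <- rep(seq_len(n_s), rows)
  start <- stop <- numeric(sum(rows))
  status <- integer(sum(rows))
  pos <- cumsum(c(0L, rows[-n_s]))
  for (i in seq_len(n_s)) {
    ev <- tt[i, seq_len(n_ev[i])]
    idx <- pos[i] + seq_len(rows[i])
    if (n_ev[i] < j) {
      start[idx] <- c(0, ev)
      stop[idx] <- c(ev, tc)
      status[idx] <- c(rep(1L, n_ev[i]), 0L)
    } else {
      start[idx] <- c(0, ev[-j])
      stop[idx] <- ev
      status[idx] <- rep(1L, j)
    }
  }
  data.frame(cluster_id = subj, subject_id = subj,
             start = start, stop = stop, status = status,
             x = x[subj], true_frailty = z[subj])
}

#' Read and write long-format counting-process data
#'
#' Plain-CSV interface for survival records: columns `cluster_id`,
#' `subject_id`, `start`, `stop`, `status`, covariate columns, and optionally
#' `true_frailty`.
#'
#' @param data a data frame of survival records.
#' @param path file path.
#' @return `read_surv_csv()` returns the validated data frame.
#' @export
write_surv_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surv_csv
#' @export
read_surv_csv <- function(path) {
  if (!file.exists(path))
    stop_domain("file not found: ", path,
                "\nexpected a CSV with header columns: cluster_id, subject_id, ",
                "start, stop, status, <covariates>[, true_frailty]")
  d <- utils::read.csv(path)
  need <- c("cluster_id", "subject_id", "start", "stop", "status")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_domain("missing required columns: ", paste(miss, collapse = ", "))
  if (any(d$start >= d$stop)) stop_domain("need 0 <= start < stop in all rows")
  if (!all(d$status %in% c(0, 1))) stop_domain("'status' must be 0/1")
  d
}
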
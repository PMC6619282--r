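#' Simulation scenario for clustered or recurrent event data
#'
#' Defines one cell of the simulation design: clustered failures (covariate
#' varying within or common to clusters) or recurrent events in calendar
#' time, with a Weibull baseline, a log-time-dependent covariate effect
#' `beta(t) = beta0 + beta1 * log(t)`, and a shared frailty with mean 1.
#'
#' @param structure `"clustered"` (binary covariate drawn per subject),
#'   `"clustered_common"` (covariate drawn per cluster) or `"recurrent"`
#'   (calendar-time recurrent events, covariate per subject).
#' @param group_size cluster size, or the number of events simulated per
#'   subject for recurrent data (each subject is followed to their
#'   `group_size`-th event or censoring; the baseline cumulative intensity
#'   at the horizon is `0.8 * group_size`, so observed event counts are
#'   comparable with a cluster of that size).
#' @param total_size total number of observations; must be divisible by
#'   `group_size`.
#' @param weibull_shape Weibull shape `alpha` of the baseline hazard
#'   (`alpha < 1` decreasing, `= 1` constant, `> 1` increasing).
#' @param beta1_level strength of the time-dependent part of the covariate
#'   effect: level 0 is proportional hazards (`beta1 = 0`); level 2 makes the
#'   effect vanish at the horizon (`beta0 + beta1 * log(horizon) = 0`); level
#'   1 is halfway between.
#' @param frailty_variance variance of the simulated frailty (0 disables it).
#' @param frailty_law `"lognormal"` or `"gamma"`, both with mean 1 and the
#'   requested variance.
#' @param censor_rate administrative censoring rate imposed by calibration
#'   (the censoring time is the `1 - censor_rate` quantile of the uncensored
#'   event-time distribution of the cell).
#' @param horizon time anchoring the baseline scale, `Lambda0(horizon) = 0.8`
#'   (clustered) or `0.8 * group_size` (recurrent).
#' @param beta0 time-constant part of the covariate effect.
#' @param covariate_p success probability of the Bernoulli covariate.
#' @return an object of class `"scenario"`.
#' @examples
#' sc <- scenario("clustered", group_size = 2, total_size = 300)
#' rs <- resolve_scenario(sc, censor = FALSE)
#' rs$weibull_scale * 50  # Lambda0(50) = 0.8
#' @export
scenario <- function(structure = c("clustered", "clustered_common", "recurrent"),
                     group_size = 2, total_size = 300, weibull_shape = 1,
                     beta1_level = 0, frailty_variance = 0,
                     frailty_law = c("lognormal", "gamma"),
                     censor_rate = 0.3, horizon = 50,
                     beta0 = log(5), covariate_p = 0.5) {
  structure <- match.arg(structure)
  frailty_law <- match.arg(frailty_law)
  if (group_size < 1 || group_size != round(group_size))
    stop_domain("'group_size' must be a positive integer")
  if (total_size %% group_size != 0)
    stop_domain("'total_size' must be divisible by 'group_size'")
  if (!beta1_level %in% 0:2)
    stop_domain("'beta1_level' must be 0, 1 or 2")
  if (frailty_variance < 0) stop_domain("'frailty_variance' must be >= 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop_domain("'censor_rate' must be in [0, 1)")
  obj <- list(structure = structure, group_size = as.integer(group_size),
              total_size = as.integer(total_size),
              weibull_shape = weibull_shape, beta1_level = beta1_level,
              frailty_variance = frailty_variance, frailty_law = frailty_law,
              censor_rate = censor_rate, horizon = horizon, beta0 = beta0,
              covariate_p = covariate_p)
  class(obj) <- "scenario"
  obj
}

#' Read scenario configuration files
#'
#' Reads one simulation cell from a flat key-value file (JSON via jsonlite,
#' or YAML via the yaml package, chosen by file extension).  Keys match the
#' arguments of [scenario()]; unknown keys are an error.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a [scenario()] object.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_domain("scenario file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_domain("the yaml package is required for YAML scenario files")
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop_domain("the jsonlite package is required for JSON scenario files")
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(scenario)))
  if (length(unknown))
    stop_domain("unknown scenario keys: ", paste(unknown, collapse = ", "))
  do.call(scenario, vals)
}

#' Resolve a scenario into all derived simulation constants
#'
#' Computes the Weibull scale from the horizon constraint, the time-dependent
#' effect slope from its level, the lognormal parameters from the moment
#' equations, and (optionally) the administrative censoring time by
#' calibration.
#'
#' @param config a [scenario()] object.
#' @param censor if `FALSE`, no censoring time is calibrated and simulated
#'   data are uncensored (recurrent processes are still truncated at the
#'   horizon).
#' @param calib_size number of subjects in the calibration sample.
#' @param seed seed for the calibration stream.
#' @return an object of class `"resolved_scenario"` with fields
#'   `weibull_scale`, `beta1`, `lognormal_mu`, `lognormal_s` (variance of the
#'   log-frailty), `censor_time` added to the scenario fields.
#' @export
resolve_scenario <- function(config, censor = TRUE, calib_size = 1e5,
                             seed = 20201L) {
  if (!inherits(config, "scenario")) stop_domain("'config' must be a scenario")
  rs <- unclass(config)
  target <- if (config$structure == "recurrent") 0.8 * config$group_size else 0.8
  rs$cumhaz_horizon <- target
  rs$weibull_scale <- target / config$horizon^config$weibull_shape
  b2 <- -config$beta0 / log(config$horizon)
  rs$beta1 <- switch(as.character(config$beta1_level),
                     "0" = 0, "1" = b2 / 2, "2" = b2)
  if (config$weibull_shape + rs$beta1 <= 0)
    stop_domain("Weibull shape ", config$weibull_shape, " with beta1 ",
                format(rs$beta1), " violates shape positivity")
  if (config$frailty_variance > 0 && config$frailty_law == "lognormal") {
    rs$lognormal_s <- log1p(config$frailty_variance)
    rs$lognormal_mu <- -rs$lognormal_s / 2
  } else {
    rs$lognormal_s <- rs$lognormal_mu <- NA_real_
  }
  rs$censor_time <- Inf
  class(rs) <- "resolved_scenario"
  if (censor) rs$censor_time <- calibrate_censoring(rs, calib_size, seed)
  rs
}

#' @export
print.scenario <- function(x, ...) {
  cat("Simulation scenario:", x$structure, "\n")
  cat(sprintf("  %d observations in groups of %d; Weibull shape %g\n",
              x$total_size, x$group_size, x$weibull_shape))
  cat(sprintf("  effect beta(t) = %.3f + beta1(level %d) log t; frailty %s var %g\n",
              x$beta0, x$beta1_level, x$frailty_law, x$frailty_variance))
  invisible(x)
}

#' @export
print.resolved_scenario <- function(x, ...) {
  cat("Resolved scenario:", x$structure, "\n")
  cat(sprintf("  scale %g (Lambda0(%g) = %g), beta1 = %.5f\n",
              x$weibull_scale, x$horizon, x$cumhaz_horizon, x$beta1))
  cat(sprintf("  censoring time %s\n", format(x$censor_time)))
  invisible(x)
}

## frailty draws with mean 1 and the configured variance
.draw_frailty <- function(rs, n) {
  v <- rs$frailty_variance
  if (v == 0) return(rep(1, n))
  if (rs$frailty_law == "lognormal") {
    exp(stats::rnorm(n, rs$lognormal_mu, sqrt(rs$lognormal_s)))
  } else {
    stats::rgamma(n, shape = 1 / v, rate = 1 / v)
  }
}

## conditional cumulative hazard Lambda(t | Z, x) = K t^a and its inverse;
## a = alpha + beta1 x, K = Z gamma alpha exp(beta0 x) / a
.cond_pars <- function(rs, z, x) {
  a <- rs$weibull_shape + rs$beta1 * x
  K <- z * rs$weibull_scale * rs$weibull_shape * exp(rs$beta0 * x) / a
  list(a = a, K = K)
}

#' Calibrate the administrative censoring time of a scenario
#'
#' Simulates one large uncensored sample from the scenario and returns the
#' `1 - censor_rate` quantile of the event times.  For clustered data this is
#' the quantile of the subjects' event times, so applying it as an
#' administrative censoring time censors `censor_rate` of subjects in
#' expectation.  For recurrent data, the calendar event times of the
#' uncensored processes (exactly `group_size` events per subject) are
#' pooled, so the calibrated time removes `censor_rate` of the events.
#'
#' @param rs a resolved scenario (the censoring time itself is ignored).
#' @param calib_size number of subjects simulated for calibration.
#' @param seed seed for the calibration stream.
#' @return the calibrated censoring time.
#' @export
calibrate_censoring <- function(rs, calib_size = 1e5, seed = 20201L) {
  if (!inherits(rs, "resolved_scenario"))
    stop_domain("'rs' must be a resolved_scenario")
  set.seed(seed)
  n <- as.integer(calib_size)
  z <- .draw_frailty(rs, n)  # marginally, one frailty per subject suffices
  x <- stats::rbinom(n, 1, rs$covariate_p)
  cp <- .cond_pars(rs, z, x)
  if (rs$structure == "recurrent") {
    ## pool the calendar event times of the truncated processes (exactly
    ## group_size events per subject when uncensored)
    ev <- as.vector(.recurrent_event_times(rs, z, x))
  } else {
    ev <- (stats::rexp(n) / cp$K)^(1 / cp$a)
  }
  stats::quantile(ev, 1 - rs$censor_rate, names = FALSE)
}
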
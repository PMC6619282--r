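#' Plot the marginal hazard-ratio attenuation of a frailty family
#'
#' Displays the population-averaged hazard ratio between two groups with a
#' conditional hazard ratio `exp(beta)` under a unit baseline hazard, the
#' curve that illustrates how frailty selection makes a time-constant
#' conditional effect look time-dependent (except for the positive stable
#' family, whose marginal hazards stay proportional).
#'
#' @param x a [frailty_family()] object.
#' @param beta conditional log hazard ratio.
#' @param tmax upper end of the time grid.
#' @param ... passed to [graphics::plot()].
#' @export
plot.frailty_family <- function(x, beta = log(5), tmax = 4, ...) {
  cv <- marginal_hr_curve(x, beta = beta, times = seq(0, tmax, length.out = 201))
  plot(cv$time, cv$hr, type = "l", xlab = "time",
       ylab = "marginal hazard ratio",
       main = paste0(x$name, " frailty (theta = ", format(x$theta), ")"),
       ylim = c(1, exp(beta)), ...)
  abline(h = c(1, exp(beta)), lty = 3)
  invisible(cv)
}

#' Plot scaled Schoenfeld residuals against time
#'
#' Scatter of the scaled Schoenfeld residuals for one covariate with a
#' lowess smooth; a horizontal trend is consistent with proportional
#' hazards.
#'
#' @param x a [fit_cox()] object.
#' @param covariate name or index of the covariate.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cox_fit <- function(x, covariate = 1L, ...) {
  r <- residuals(x, "scaled_schoenfeld")
  tt <- attr(r, "time")
  y <- r[, covariate]
  plot(tt, y, xlab = "time", ylab = paste("scaled Schoenfeld,",
                                          colnames(r)[covariate][1]), ...)
  lines(stats::lowess(tt, y), col = 2, lwd = 2)
  abline(h = coef(x)[covariate], lty = 3)
  invisible(r)
}

#' Plot the estimated cumulative baseline hazard of a frailty fit
#'
#' @param x a [fit_frailty()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.frailty_fit <- function(x, ...) {
  bl <- x$baseline
  plot(bl$time, cumsum(bl$hazard), type = "s", xlab = "time",
       ylab = "cumulative baseline hazard",
       main = paste0("shared frailty fit (", x$family$name, ")"), ...)
  invisible(bl)
}
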
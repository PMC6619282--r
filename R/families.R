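#' Frailty distribution families
#'
#' Constructs a frailty family object holding the distribution name and its
#' association parameter `theta`.  All families are parametrized so that the
#' frailty `Z` has mean 1; for the gamma, inverse Gaussian and lognormal
#' families the variance is `1/theta`, so large `theta` means weak frailty.
#' The positive stable family has no finite variance; its Laplace transform is
#' `exp(-c^b)` with `b = 1/(1 + theta)`, so `theta = 0` is the degenerate
#' no-frailty case `Z == 1`.  Should a different stable-scale convention be
#' preferred, only the mapping from `theta` to `b` in [ps_index()] needs to
#' change.
#'
#' @param name one of `"gamma"`, `"inverse_gaussian"`, `"positive_stable"`,
#'   `"lognormal"`.  The lognormal family supports the transform, derivatives
#'   and hazard-ratio curves (by quadrature) and is used for data generation;
#'   it is not supported for model fitting.
#' @param theta positive association parameter (nonnegative for the positive
#'   stable family).
#' @return an object of class `"frailty_family"`.
#' @examples
#' fam <- frailty_family("gamma", theta = 2)
#' laplace(fam, 1)
#' posterior_expectation(fam, n_events = 1, cumhaz = 1)
#' @export
frailty_family <- function(name = c("gamma", "inverse_gaussian",
                                    "positive_stable", "lognormal"),
                           theta) {
  name <- match.arg(name)
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta))
    stop_domain("'theta' must be a single number")
  if (name == "positive_stable") {
    if (theta < 0) stop_domain("positive stable family requires theta >= 0")
  } else if (theta <= 0) {
    stop_domain("family '", name, "' requires theta > 0")
  }
  structure(list(name = name, theta = theta), class = "frailty_family")
}

#' @export
print.frailty_family <- function(x, ...) {
  cat("Frailty family:", x$name, "\n")
  cat("  theta =", format(x$theta), "\n")
  if (x$name == "positive_stable") {
    cat("  stable index b = 1/(1+theta) =", format(ps_index(x$theta)), "\n")
    cat("  E[Z] and Var[Z] not finite\n")
  } else {
    cat("  E[Z] = 1, Var[Z] = 1/theta =", format(1 / x$theta), "\n")
  }
  invisible(x)
}

#' @rdname frailty_family
#' @export
ps_index <- function(theta) 1 / (1 + theta)

.check_family <- function(family) {
  if (!inherits(family, "frailty_family"))
    stop_domain("'family' must be a frailty_family object")
  family
}

.check_cumhaz <- function(c) {
  if (any(!is.finite(c)) || any(c < 0))
    stop_domain("cumulative hazard argument must be finite and >= 0")
  c
}

## lognormal parameters on the log scale: Var[Z] = 1/theta,
## s = Var[log Z] = log(1 + 1/theta), mu = -s/2 so that E[Z] = 1
.lognormal_pars <- function(theta) {
  s <- log1p(1 / theta)
  list(mu = -s / 2, sig = sqrt(s))
}

## E[Z^k exp(-cZ)] for lognormal Z by adaptive quadrature on the normal scale
.lognormal_moment <- function(theta, k, c) {
  p <- .lognormal_pars(theta)
  vapply(c, function(ci) {
    stats::integrate(function(u) {
      v <- p$mu + p$sig * u
      e <- stats::dnorm(u, log = TRUE) + k * v
      if (ci > 0) e <- e - ci * exp(v)
      exp(e)
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
}

## ---------------------------------------------------------------------------
## The transform is written as L(c) = exp(-h(c)) with h a Bernstein function.
## Signed derivatives are generated from the nonnegative coefficients
## a_m(c) = (-1)^(m-1) h^(m)(c) through the Leibniz recursion
##   Q_0 = 1,  Q_{n+1} = sum_j choose(n, j) a_{j+1} Q_{n-j},
## where Q_n = (-1)^n L^(n)(c) / L(c) > 0.  All recursion terms are positive,
## so the computation is numerically stable; a log-space fallback catches
## overflow at high orders.
## ---------------------------------------------------------------------------

## h(c) = -log L(c), vectorized in c
.ff_h <- function(family, c) {
  th <- family$theta
  switch(family$name,
    gamma = th * log1p(c / th),
    inverse_gaussian = th * (sqrt(1 + 2 * c / th) - 1),
    positive_stable = {
      b <- ps_index(th)
      ifelse(c == 0, 0, c^b)
    },
    lognormal = -log(.lognormal_moment(th, 0, c))
  )
}

## log a_m(c) for m = 1..mmax at a scalar c >= 0; matrix mmax x 1 semantics
## (returned as a vector).  Defined for gamma, inverse Gaussian and positive
## stable; the lognormal has no closed Bernstein coefficients.
.ff_log_a <- function(family, mmax, c) {
  th <- family$theta
  m <- seq_len(mmax)
  switch(family$name,
    gamma = log(th) + lgamma(m) - m * log(th + c),
    inverse_gaussian =
      (m - 1) * log(2 / th) + lgamma(m - 0.5) - lgamma(0.5) +
        (0.5 - m) * log1p(2 * c / th),
    positive_stable = {
      b <- ps_index(th)
      if (c == 0)
        stop_domain("positive stable derivatives require c > 0")
      ## |b (b-1) ... (b-m+1)| = b * prod_{i=1}^{m-1} (i - b)
      cum <- cumsum(c(0, log(seq_len(max(mmax - 1, 0)) - b)))
      log(b) + cum + (b - m) * log(c)
    },
    stop_domain("no closed-form derivatives for family '", family$name, "'")
  )
}

## Q_n(c) = (-1)^n L^(n)(c)/L(c) for n = 0..nmax at scalar c; returns log Q.
.ff_logQ_scalar <- function(family, nmax, c) {
  if (nmax == 0) return(0)
  if (nmax > 30 && family$name == "positive_stable")
    stop_domain("positive stable derivatives supported up to order 30 ",
                "(requested ", nmax, ")")
  la <- .ff_log_a(family, nmax, c)
  logQ <- numeric(nmax + 1)  # logQ[n+1] = log Q_n
  for (n in 0:(nmax - 1)) {
    j <- 0:n
    logQ[n + 2] <- logsumexp(lchoose(n, j) + la[j + 1] + logQ[n - j + 1])
  }
  logQ
}

## Leibniz recursion vectorized over observations: log Q_{n_i}(c_i) in linear
## space column-wise, with a scalar log-space fallback on under/overflow.
.ff_logQ_vec <- function(family, n, c) {
  nmax <- max(n)
  if (nmax == 0) return(numeric(length(n)))
  if (nmax > 30 && family$name == "positive_stable")
    stop_domain("positive stable derivatives supported up to order 30 ",
                "(requested ", nmax, ")")
  nc <- length(c)
  A <- matrix(0, nmax, nc)
  for (m in seq_len(nmax)) A[m, ] <- exp(.ff_log_a_vec(family, m, c))
  Q <- matrix(0, nmax + 1L, nc)
  Q[1L, ] <- 1
  for (k in 0:(nmax - 1L)) {
    j <- 0:k
    ch <- choose(k, j)
    Q[k + 2L, ] <- ch %*% (A[j + 1L, , drop = FALSE] * Q[k - j + 1L, , drop = FALSE])
  }
  out <- log(Q[cbind(n + 1L, seq_len(nc))])
  bad <- which(!is.finite(out) & n > 0)
  for (i in bad) out[i] <- .ff_logQ_scalar(family, n[i], c[i])[n[i] + 1L]
  out
}

## log a_m(c) for one order m, vectorized in c
.ff_log_a_vec <- function(family, m, c) {
  th <- family$theta
  switch(family$name,
    gamma = log(th) + lgamma(m) - m * log(th + c),
    inverse_gaussian =
      (m - 1) * log(2 / th) + lgamma(m - 0.5) - lgamma(0.5) +
        (0.5 - m) * log1p(2 * c / th),
    positive_stable = {
      b <- ps_index(th)
      if (any(c == 0)) stop_domain("positive stable derivatives require c > 0")
      log(b) + sum(log(seq_len(m - 1) - b)) + (b - m) * log(c)
    },
    stop_domain("no closed-form derivatives for family '", family$name, "'")
  )
}

## log Q_{n_i}(c_i) vectorized over pairs; closed forms for gamma and
## inverse Gaussian, Leibniz recursion for the positive stable.
.ff_logQ_pairs <- function(family, n, c) {
  th <- family$theta
  switch(family$name,
    gamma = lgamma(th + n) - lgamma(th) - n * log(th) - n * log1p(c / th),
    inverse_gaussian = {
      x <- th * sqrt(1 + 2 * c / th)
      (n / 2) * (log(th) - log(th + 2 * c)) +
        log(besselK(x, n - 0.5, expon.scaled = TRUE)) -
        log(besselK(x, 0.5, expon.scaled = TRUE))
    },
    positive_stable = .ff_logQ_vec(family, n, c),
    stop_domain("log Q not available for family '", family$name, "'")
  )
}

#' Laplace transform of a frailty distribution
#'
#' `laplace()` evaluates `L(c) = E[exp(-cZ)]`; `laplace_derivative()`
#' evaluates the k-th derivative `L^(k)(c)`, which carries sign `(-1)^k` by
#' complete monotonicity.
#'
#' @param family a [frailty_family()] object.
#' @param c nonnegative argument (vectorized).  The positive stable family
#'   requires `c > 0` when `k >= 1`.
#' @param k derivative order, a nonnegative integer.
#' @return `laplace()` returns values in `(0, 1]`; `laplace_derivative()`
#'   returns `L^(k)(c)`.
#' @examples
#' laplace(frailty_family("gamma", 1), 1)        # (1 + 1)^-1 = 0.5
#' laplace_derivative(frailty_family("gamma", 1), k = 1, c = 1)  # -0.25
#' @export
laplace <- function(family, c) {
  .check_family(family)
  .check_cumhaz(c)
  exp(-.ff_h(family, c))
}

#' @rdname laplace
#' @export
laplace_derivative <- function(family, k, c) {
  .check_family(family)
  .check_cumhaz(c)
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != round(k))
    stop_domain("'k' must be a single nonnegative integer")
  if (k == 0) return(laplace(family, c))
  if (family$name == "lognormal")
    return((-1)^k * .lognormal_moment(family$theta, k, c))
  sign <- (-1)^k
  vapply(c, function(ci) {
    lq <- .ff_logQ_scalar(family, k, ci)[k + 1]
    sign * exp(lq - .ff_h(family, ci))
  }, numeric(1))
}

#' Posterior expectation of the frailty
#'
#' The conditional mean of `Z` given `n_events` observed events and an
#' accumulated conditional cumulative hazard `cumhaz` in the cluster (or
#' subject) history: `-L^(n+1)(cumhaz) / L^(n)(cumhaz)`.
#'
#' @inheritParams laplace
#' @param n_events number of observed events (vectorized).
#' @param cumhaz accumulated conditional cumulative hazard (vectorized).
#' @return positive posterior means, recycled to the common length.
#' @examples
#' posterior_expectation(frailty_family("gamma", 2), 1, 1)  # (2+1)/(2+1) = 1
#' @export
posterior_expectation <- function(family, n_events, cumhaz) {
  .check_family(family)
  .check_cumhaz(cumhaz)
  if (any(n_events < 0) || any(n_events != round(n_events)))
    stop_domain("'n_events' must be nonnegative integers")
  nn <- pmax(length(n_events), length(cumhaz))
  n <- rep_len(n_events, nn)
  c <- rep_len(cumhaz, nn)
  th <- family$theta
  switch(family$name,
    gamma = (th + n) / (th + c),
    lognormal = mapply(function(ni, ci) {
      .lognormal_moment(th, ni + 1, ci) / .lognormal_moment(th, ni, ci)
    }, n, c),
    ## IG and PS through log Q ratios
    exp(.ff_logQ_pairs(family, n + 1, c) - .ff_logQ_pairs(family, n, c))
  )
}

#' Marginal hazard ratio under a shared frailty model
#'
#' Ratio of the marginal (population-averaged) hazards of survivors in the
#' `x = 1` and `x = 0` groups when the conditional model has hazard ratio
#' `exp(beta)` and baseline cumulative hazard `cumhaz0`, for univariate data.
#' Frailty selection attenuates the conditional hazard ratio over time for
#' finite-variance families; the positive stable family leaves the marginal
#' hazards proportional with ratio `exp(beta * b)`.
#'
#' @inheritParams laplace
#' @param beta conditional log hazard ratio.
#' @param cumhaz0 baseline cumulative hazard at the evaluation time
#'   (vectorized).
#' @return positive marginal hazard ratios.
#' @examples
#' fam <- frailty_family("gamma", 4)
#' marginal_hazard_ratio(fam, log(5), 1)  # 5 * (4 + 1) / (4 + 5) = 25/9
#' @export
marginal_hazard_ratio <- function(family, beta, cumhaz0) {
  .check_family(family)
  .check_cumhaz(cumhaz0)
  if (family$name == "positive_stable") {
    ## the posterior-mean ratio collapses to a constant:
    ## Q1(c) = b c^(b-1), so exp(beta) Q1(L e^beta)/Q1(L) = exp(beta b)
    return(rep_len(exp(beta * ps_index(family$theta)), length(cumhaz0)))
  }
  exp(beta) * posterior_expectation(family, 0, cumhaz0 * exp(beta)) /
    posterior_expectation(family, 0, cumhaz0)
}

#' Median concordance of bivariate survival under shared frailty
#'
#' For clusters of size 2 with a shared frailty, the median concordance is
#' `kappa = 4 L(2 L^{-1}(1/2)) - 1`, the sign-concordance of the two event
#' times about their marginal medians.  Closed-form inverses of the Laplace
#' transform are used where available, otherwise a bracketed root search on
#' `[1e-12, 1e6]` to absolute tolerance 1e-10.
#'
#' @inheritParams laplace
#' @return a number in `[-1, 1]`.
#' @examples
#' median_concordance(frailty_family("gamma", 1))  # 1/3
#' @export
median_concordance <- function(family) {
  .check_family(family)
  th <- family$theta
  cstar <- switch(family$name,
    gamma = th * (2^(1 / th) - 1),
    inverse_gaussian = log(2) + log(2)^2 / (2 * th),
    positive_stable = {
      b <- ps_index(th)
      log(2)^(1 / b)
    },
    stop_domain("median concordance not implemented for family '",
                family$name, "'")
  )
  ## guard the closed forms with the generic bracketed inverse
  if (!is.finite(cstar) || abs(laplace(family, cstar) - 0.5) > 1e-8)
    cstar <- laplace_inverse(family, 0.5)
  4 * laplace(family, 2 * cstar) - 1
}

#' @rdname median_concordance
#' @param p target transform value in (0, 1).
#' @export
laplace_inverse <- function(family, p) {
  .check_family(family)
  if (p <= 0 || p >= 1) stop_domain("'p' must be in (0, 1)")
  f <- function(c) laplace(family, c) - p
  if (f(1e-12) < 0) return(0)
  if (f(1e6) > 0) stop_domain("laplace_inverse: root beyond bracket [1e-12, 1e6]")
  stats::uniroot(f, c(1e-12, 1e6), tol = 1e-10)$root
}

#' Marginal hazard-ratio curves over time
#'
#' Convenience wrapper evaluating [marginal_hazard_ratio()] on a time grid
#' for a unit baseline hazard (`Lambda0(t) = rate * t`), the setting in which
#' the attenuation of a conditional hazard ratio by frailty selection is
#' usually displayed.
#'
#' @inheritParams marginal_hazard_ratio
#' @param times evaluation times.
#' @param rate constant baseline hazard rate.
#' @return a data frame with columns `time` and `hr`.
#' @export
marginal_hr_curve <- function(family, beta = log(5), times = seq(0, 4, by = 0.05),
                              rate = 1) {
  data.frame(time = times,
             hr = marginal_hazard_ratio(family, beta, rate * times))
}
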
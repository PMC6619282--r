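## Independent oracles used across the suite.  These are written directly
## from the defining formulas (loops over risk sets, quadrature-free closed
## forms) so that they share no code with the package internals.

## Breslow log partial likelihood by explicit risk-set loops
breslow_pl_oracle <- function(beta, start, stop, status, X, offset = NULL) {
  X <- as.matrix(X)
  if (is.null(offset)) offset <- numeric(nrow(X))
  eta <- offset + drop(X %*% beta)
  ll <- 0
  for (r in which(status == 1)) {
    at_risk <- which(start < stop[r] & stop >= stop[r])
    ll <- ll + eta[r] - log(sum(exp(eta[at_risk])))
  }
  ll
}

## random small counting-process dataset
random_surv_data <- function(n, p = 1, seed) {
  set.seed(seed)
  st <- ifelse(stats::runif(n) < 0.5, 0, stats::runif(n, 0, 1))
  sp <- st + stats::rexp(n)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  data.frame(start = st, stop = sp,
             status = stats::rbinom(n, 1, 0.7), X)
}

## mean-1 inverse Gaussian random draws (Michael-Schucany-Haas)
rinvgauss1 <- function(n, theta) {
  nu <- stats::rnorm(n)^2
  x <- 1 + (nu - sqrt(4 * theta * nu + nu^2)) / (2 * theta)
  u <- stats::runif(n)
  ifelse(u <= 1 / (1 + x), x, 1 / x)
}

## positive stable random draws, L(c) = exp(-c^b) (Chambers-Mallows-Stuck)
rposstable <- function(n, b) {
  if (b == 1) return(rep(1, n))
  u <- stats::runif(n, 0, pi)
  e <- stats::rexp(n)
  (sin(b * u) / sin(u)^(1 / b)) *
    (sin((1 - b) * u) / e)^((1 - b) / b)
}

## gamma-frailty marginal log likelihood from scratch (closed form),
## given baseline hazard increments at the event times
gamma_marginal_oracle <- function(theta, beta, log_h, d) {
  ev_t <- sort(unique(d$stop[d$status == 1]))
  h <- exp(log_h)
  cumh <- cumsum(h)
  L0 <- function(t) c(0, cumh)[findInterval(t, ev_t) + 1]
  eta <- drop(as.matrix(d[, grep("^x", names(d)), drop = FALSE]) %*% beta)
  Lam_row <- exp(eta) * (L0(d$stop) - L0(d$start))
  Lam <- tapply(Lam_row, d$cluster_id, sum)
  N <- tapply(d$status, d$cluster_id, sum)
  cl_term <- sum(lgamma(theta + N) - lgamma(theta) - N * log(theta) -
                   (theta + N) * log(1 + Lam / theta))
  ## event terms: each event contributes its linear predictor and the log
  ## baseline increment at its time
  ev <- d$status == 1
  cl_term + sum(eta[ev]) + sum(log(h[match(d$stop[ev], ev_t)]))
}
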
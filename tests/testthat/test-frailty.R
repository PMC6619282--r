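make_frailty_data <- function(n_cl, size, var = 0.5, seed = 1,
                              law = "gamma") {
  rs <- resolve_scenario(scenario("clustered", size, n_cl * size,
                                  frailty_variance = var, frailty_law = law),
                         censor = FALSE)
  simulate_dataset(rs, seed = seed)
}

test_that("marginal log likelihood matches the gamma closed form", {
  d <- make_frailty_data(12, 3, var = 0.5, seed = 42)
  fit <- fit_frailty(Surv(stop, status) ~ x + cluster(cluster_id), d, "gamma")
  ## the exported evaluator agrees with the value reported by the fit
  ll <- marginal_loglik(d, fit$family, coef(fit), fit$baseline)
  expect_equal(ll, fit$marginal_loglik, tolerance = 1e-8)
  ## and with a from-scratch closed-form implementation
  oracle <- gamma_marginal_oracle(fit$theta_hat, coef(fit),
                                  log(fit$baseline$hazard), d)
  expect_equal(ll, unname(oracle), tolerance = 1e-8)
})

test_that("vanishing frailty recovers the no-frailty likelihood", {
  d <- make_frailty_data(10, 2, var = 0, seed = 7)
  cox <- fit_cox(Surv(stop, status) ~ x + cluster(cluster_id), d)
  ll_inf <- marginal_loglik(d, frailty_family("gamma", 1e8),
                            coef(cox), cox$baseline)
  expect_lt(abs(ll_inf - cox$loglik_full), 1e-3)
  ## single censored cluster contributes a log survivor probability <= 0
  fam <- frailty_family("gamma", 2)
  one <- data.frame(cluster_id = 1, start = 0, stop = 5, status = 0, x = 1)
  base <- cox$baseline
  ll1 <- marginal_loglik(rbind(one, data.frame(cluster_id = 2, start = 0,
                                               stop = d$stop[d$status == 1],
                                               status = d$status[d$status == 1],
                                               x = 0)),
                         fam, c(x = 0.2), base)
  expect_true(is.finite(ll1))
})

test_that("EM increases the marginal likelihood and matches direct
          maximization on tiny data", {
  d <- make_frailty_data(5, 3, var = 1, seed = 9)
  prep <- nphfrailty:::cox_prep(d$start, d$stop, d$status,
                                matrix(d$x, dimnames = list(NULL, "x")),
                                d$cluster_id)
  ci <- nphfrailty:::.cluster_index(prep)
  em <- nphfrailty:::.profile_em(prep, ci, frailty_family("gamma", 1.5),
                                 frailty_control(), track = TRUE)
  expect_true(all(diff(em$trace) > -1e-8))
  ## profile EM against joint numerical maximization over (beta, jumps)
  fit <- fit_frailty(Surv(stop, status) ~ x + cluster(cluster_id), d, "gamma")
  K <- nrow(fit$baseline)
  direct <- function(theta) {
    obj <- function(par) {
      -gamma_marginal_oracle(theta, par[1], par[2:(K + 1)], d)
    }
    o <- stats::optim(c(coef(fit), log(fit$baseline$hazard)), obj,
                      method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    -o$value
  }
  ## at theta-hat the EM fixed point attains the directly maximized value
  expect_equal(fit$marginal_loglik, direct(fit$theta_hat), tolerance = 1e-4)
  ## and no nearby theta beats the profile maximum
  lls <- vapply(fit$theta_hat * c(0.5, 0.75, 1.5, 2), direct, numeric(1))
  expect_true(all(lls <= fit$marginal_loglik + 1e-4 * abs(fit$marginal_loglik)))
})

test_that("frailty variance is recovered from gamma-frailty data", {
  d <- make_frailty_data(500, 5, var = 0.5, seed = 2024, law = "gamma")
  fit <- fit_frailty(Surv(stop, status) ~ x + cluster(cluster_id), d, "gamma")
  expect_gt(fit$var_hat, 0.35)
  expect_lt(fit$var_hat, 0.65)
  ## beta is recovered too (conditional effect log 5)
  expect_lt(abs(unname(coef(fit)["x"]) - log(5)), 0.15)
})

test_that("null data give near-zero variance estimates", {
  small <- 0
  for (r in 1:10) {
    d <- make_frailty_data(300, 5, var = 0, seed = 100 + r)
    fit <- fit_frailty(Surv(stop, status) ~ x + cluster(cluster_id), d,
                       "gamma")
    small <- small + (fit$var_hat < 0.05)
  }
  expect_gte(small, 9)
})

test_that("boundary-mixture LRT and profile CI correspond", {
  reject <- lower0 <- logical(0)
  for (r in 1:8) {
    d <- make_frailty_data(60, 2, var = if (r <= 4) 0 else 0.8,
                           seed = 300 + r, law = "gamma")
    fit <- fit_frailty(Surv(stop, status) ~ x + cluster(cluster_id), d,
                       "gamma", ci_variance = TRUE)
    ht <- lrt_no_frailty(fit)
    expect_equal(ht$p_value,
                 0.5 * stats::pchisq(fit$lrt$stat, 1, lower.tail = FALSE))
    if (fit$lrt$stat == 0) expect_equal(ht$p_value, 0.5)
    reject <- c(reject, ht$p_value < 0.05)
    lower0 <- c(lower0, unname(fit$ci_var[1]) == 0)
    expect_gte(fit$marginal_loglik, fit$loglik_null - 1e-6)
  }
  ## the CI lower bound is zero exactly when the test does not reject
  expect_identical(reject, !lower0)
  expect_true(any(reject) && any(!reject))
})

test_that("positive stable fit is insensitive to within-cluster
          nonproportionality and caps derivative order", {
  rs <- resolve_scenario(scenario("clustered", 2, 200, beta1_level = 2),
                         censor = FALSE)
  d <- simulate_dataset(rs, seed = 17)
  fit <- fit_frailty(Surv(stop, status) ~ x + cluster(cluster_id), d,
                     "positive_stable")
  expect_true(is.na(fit$var_hat))
  expect_true(fit$theta_hat >= 0)
  expect_gte(fit$lrt$stat, 0)
  ## the CI is reported on the association parameter itself
  ci <- profile_ci_variance(fit)
  expect_identical(attr(ci, "parameter"), "theta")
  expect_identical(unname(ci[1]) == 0, !(fit$lrt$p < 0.05))
  expect_error(laplace_derivative(frailty_family("positive_stable", 1),
                                  31, 1), "order 30")
})
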
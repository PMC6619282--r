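test_that("permutation-moment heterogeneity test matches an explicit
          permutation reference", {
  set.seed(5)
  worst <- 0
  for (r in 1:20) {
    vv <- sample(c(0, 0.2, 0.4), 1)
    rs <- resolve_scenario(scenario("clustered", sample(c(2, 3, 5), 1), 60,
                                    beta1_level = 0, frailty_variance = vv),
                          censor = FALSE)
    d <- simulate_dataset(rs, seed = r + 500)
    fc <- fit_cox(Surv(stop, status) ~ x + cluster(cluster_id), d)
    p_analytic <- ca_test(fc, method = "permutation")$p_value
    m <- residuals(fc, "martingale")
    m <- m - mean(m)
    f <- factor(d$cluster_id, levels = unique(d$cluster_id))
    Tobs <- sum(rowsum(m, f)^2)
    Tp <- replicate(2000, sum(rowsum(sample(m), f)^2))
    p_perm <- (1 + sum(Tp >= Tobs)) / 2001
    worst <- max(worst, abs(p_analytic - p_perm))
  }
  expect_lt(worst, 0.05)
})

make_frailty_data_diag <- function() {
  ## pairs built from one event and one long-censored record have negative
  ## within-pair residual products by construction
  n <- 40
  data.frame(cluster_id = rep(1:(n / 2), each = 2), start = 0,
             stop = rep(c(1, 10), n / 2) + seq_len(n) * 1e-3,
             status = rep(c(1, 0), n / 2), x = stats::rbinom(n, 1, 0.5))
}

test_that("heterogeneity test is calibrated under the null and degenerates
          gracefully", {
  rs <- resolve_scenario(scenario("clustered", 3, 150), calib_size = 2e4,
                         seed = 3)
  rej <- sapply(1:200, function(r) {
    d <- simulate_dataset(rs, seed = 4000 + r)
    fc <- fit_cox(Surv(stop, status) ~ x + cluster(cluster_id), d)
    c(mart = ca_test(fc)$p_value < 0.05,
      perm = ca_test(fc, method = "permutation")$p_value < 0.05)
  })
  ## nominal 5%: martingale version may be mildly conservative
  expect_gt(mean(rej["mart", ]), 0.003)
  expect_lt(mean(rej["mart", ]), 0.10)
  expect_gt(mean(rej["perm", ]), 0.01)
  expect_lt(mean(rej["perm", ]), 0.11)
  ## all clusters of size one: no within-cluster pairs, the conditional
  ## (permutation) test is degenerate
  d1 <- data.frame(cluster_id = 1:20, start = 0,
                   stop = stats::rexp(20) + 0.1,
                   status = rep(0:1, 10), x = rep(0:1, each = 10))
  f1 <- fit_cox(Surv(stop, status) ~ x + cluster(cluster_id), d1)
  p1 <- ca_test(f1, method = "permutation")
  expect_true(is.nan(p1$p_value))
  expect_identical(p1$flag, "degenerate")
  ## exactly cancelling within-cluster residuals: no between-cluster excess,
  ## statistic driven negative, one-sided p near 1
  d2 <- make_frailty_data_diag()
  f2 <- fit_cox(Surv(stop, status) ~ x + cluster(cluster_id), d2)
  pair <- rep(seq_len(nrow(d2) / 2), each = 2)
  canc <- ca_test(f2, method = "permutation",
                  cluster = pair)$p_value
  expect_gt(canc, 0.5)
})

test_that("proportional hazards test is calibrated and powerful", {
  ## null: p-values uniform over replicates
  rs <- resolve_scenario(scenario("clustered", 1, 200), calib_size = 2e4,
                         seed = 8)
  ps <- sapply(1:200, function(r) {
    d <- simulate_dataset(rs, seed = 6000 + r)
    zph_test(fit_cox(Surv(stop, status) ~ x, d))$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  ## power: an effect reversing sign at the median is always caught
  set.seed(10)
  for (r in 1:5) {
    n <- 2000
    x <- stats::rbinom(n, 1, 0.5)
    ## piecewise exponential: rate exp(x) before t = 1, exp(-x) after
    t1 <- stats::rexp(n, exp(x))
    tt <- ifelse(t1 < 1, t1, 1 + stats::rexp(n, exp(-x)))
    d <- data.frame(start = 0, stop = tt, status = 1, x = x)
    expect_lt(zph_test(fit_cox(Surv(stop, status) ~ x, d))$p_value, 1e-4)
  }
  ## guard: more covariates than events
  dd <- data.frame(start = 0, stop = c(1, 2, 3), status = c(1, 0, 0),
                   a = c(1, 0, 1), b = c(0.3, 0.7, 0.1))
  expect_error(zph_test(fit_cox(Surv(stop, status) ~ a + b, dd)),
               "fewer events")
})
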
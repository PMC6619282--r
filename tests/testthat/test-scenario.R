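test_that("scenario resolution derives the design constants", {
  rs <- resolve_scenario(scenario("clustered", 2, 300, weibull_shape = 1),
                         censor = FALSE)
  expect_equal(rs$weibull_scale, 0.8 / 50)
  expect_equal(rs$weibull_scale * 50^rs$weibull_shape, 0.8, tolerance = 1e-12)
  rs8 <- resolve_scenario(scenario("clustered", 2, 300, weibull_shape = 0.8),
                          censor = FALSE)
  expect_equal(rs8$weibull_scale * 50^0.8, 0.8, tolerance = 1e-12)
  ## recurrent scale carries the events-per-subject factor
  rr <- resolve_scenario(scenario("recurrent", 3, 300), censor = FALSE)
  expect_equal(rr$weibull_scale * 50, 0.8 * 3, tolerance = 1e-12)
  ## time-dependent effect levels: beta0 + beta1 log(50) = 0 at level 2
  r2 <- resolve_scenario(scenario("clustered", 2, 300, beta1_level = 2),
                         censor = FALSE)
  expect_equal(r2$beta0 + r2$beta1 * log(50), 0, tolerance = 1e-12)
  expect_equal(round(r2$beta1, 2), -0.41)
  r1 <- resolve_scenario(scenario("clustered", 2, 300, beta1_level = 1),
                         censor = FALSE)
  expect_equal(r1$beta1, r2$beta1 / 2)
  expect_equal(round(r1$beta1, 2), -0.21)
  ## lognormal moment equations: mean-1 frailty
  rl <- resolve_scenario(scenario("clustered", 2, 300,
                                  frailty_variance = 0.25), censor = FALSE)
  expect_equal(rl$lognormal_s, log(1.25))
  expect_equal(rl$lognormal_mu, -log(1.25) / 2)
  expect_equal(exp(rl$lognormal_mu + rl$lognormal_s / 2), 1)
  ## Weibull shape positivity guard
  expect_error(resolve_scenario(scenario("clustered", 2, 300,
                                         weibull_shape = 0.3,
                                         beta1_level = 2), censor = FALSE),
               "positivity")
  expect_error(scenario("clustered", 2, 301), "divisible")
})

test_that("scenario files round-trip through the key-value reader", {
  path <- tempfile(fileext = ".json")
  writeLines('{"structure": "recurrent", "group_size": 5,
               "total_size": 900, "weibull_shape": 0.8,
               "beta1_level": 1, "frailty_variance": 0.25}', path)
  sc <- read_scenario(path)
  expect_s3_class(sc, "scenario")
  expect_equal(sc$group_size, 5L)
  expect_equal(sc$weibull_shape, 0.8)
  writeLines('{"structure": "clustered", "bogus_key": 1}', path)
  expect_error(read_scenario(path), "bogus_key")
  ypath <- tempfile(fileext = ".yaml")
  writeLines(c("structure: clustered_common", "group_size: 3",
               "total_size: 300"), ypath)
  expect_equal(read_scenario(ypath)$structure, "clustered_common")
})

test_that("simulated frailty has the configured moments", {
  for (law in c("lognormal", "gamma")) {
    rs <- resolve_scenario(scenario("clustered", 1, 1e5,
                                    frailty_variance = 0.25,
                                    frailty_law = law), censor = FALSE)
    d <- simulate_dataset(rs, seed = 31)
    z <- d$true_frailty
    expect_lt(abs(mean(z) - 1), 3 * stats::sd(z) / sqrt(length(z)))
    expect_lt(abs(stats::var(z) - 0.25), 0.02)
  }
})

test_that("censoring calibration hits the target rate", {
  ## homogeneous exponential special case: closed-form 0.7 quantile
  rs <- resolve_scenario(scenario("clustered", 2, 300, covariate_p = 0),
                         censor = FALSE)
  tc <- calibrate_censoring(rs, calib_size = 1e5, seed = 5)
  expect_equal(tc, -log(0.3) / rs$weibull_scale, tolerance = 0.01)
  ## Bernoulli-covariate mixture against a brute-force quantile oracle
  rsx <- resolve_scenario(scenario("clustered", 2, 300), censor = FALSE)
  tcx <- calibrate_censoring(rsx, calib_size = 1e5, seed = 6)
  set.seed(99)
  nn <- 1e6
  x <- stats::rbinom(nn, 1, 0.5)
  tt <- stats::rexp(nn, rate = rsx$weibull_scale * exp(log(5) * x))
  expect_equal(tcx, unname(stats::quantile(tt, 0.7)), tolerance = 0.005)
  ## imposed administrative censoring removes ~30% of subjects
  rs2 <- resolve_scenario(scenario("clustered", 2, 1e5, weibull_shape = 0.8,
                                   beta1_level = 2, frailty_variance = 0.25),
                          calib_size = 1e5, seed = 7)
  d <- simulate_dataset(rs2, seed = 8)
  expect_lt(abs(mean(d$status == 0) - 0.30), 0.01)
  ## recurrent: calibrated time removes ~30% of the pooled event times
  rr <- resolve_scenario(scenario("recurrent", 2, 2e4), calib_size = 1e5,
                         seed = 9)
  du <- simulate_dataset(resolve_scenario(scenario("recurrent", 2, 2e4),
                                          censor = FALSE), seed = 10)
  ev <- du$stop[du$status == 1]   # exactly j per subject when uncensored
  expect_lt(abs(mean(ev <= rr$censor_time) - 0.70), 0.015)
})
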
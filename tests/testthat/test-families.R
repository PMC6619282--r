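test_that("Laplace transforms match closed forms and basic limits", {
  ga1 <- frailty_family("gamma", 1)
  expect_equal(laplace(ga1, 1), 0.5)
  expect_equal(laplace(ga1, 0), 1)
  expect_equal(laplace(frailty_family("inverse_gaussian", 3), 0), 1)
  expect_equal(laplace(frailty_family("lognormal", 3), 0), 1)
  ## degenerate stable index: Z == 1
  expect_equal(laplace(frailty_family("positive_stable", 0), 1), exp(-1))
  expect_equal(laplace_derivative(ga1, 1, 1), -0.25)
  ## zeroth derivative is the transform itself
  for (fam in list(ga1, frailty_family("inverse_gaussian", 2),
                   frailty_family("positive_stable", 1))) {
    expect_equal(laplace_derivative(fam, 0, 0.7), laplace(fam, 0.7))
  }
  expect_error(laplace(ga1, -1), "domain|>= 0")
  expect_error(frailty_family("gamma", -2), "theta")
  expect_error(laplace_derivative(frailty_family("positive_stable", 1), 1, 0),
               "c > 0")
})

test_that("derivatives are completely monotone and match finite differences", {
  fams <- list(frailty_family("gamma", 0.7),
               frailty_family("inverse_gaussian", 2),
               frailty_family("positive_stable", 1.5))
  for (fam in fams) {
    for (k in 0:10) {
      v <- laplace_derivative(fam, k, c(0.05, 0.5, 2, 8, 20))
      expect_true(all((-1)^k * v > 0), label = paste(fam$name, "k =", k))
    }
  }
  ## Richardson-extrapolated third difference of the transform
  ig <- frailty_family("inverse_gaussian", 2)
  d3 <- function(h) {
    (-laplace(ig, 0.7 - 2 * h) + 2 * laplace(ig, 0.7 - h) -
       2 * laplace(ig, 0.7 + h) + laplace(ig, 0.7 + 2 * h)) / (2 * h^3)
  }
  fd <- (4 * d3(5e-3 / 2) - d3(5e-3)) / 3
  expect_equal(laplace_derivative(ig, 3, 0.7), fd, tolerance = 1e-6)
  ## lognormal mean and variance through derivatives at 0
  ln <- frailty_family("lognormal", 4)
  expect_equal(-laplace_derivative(ln, 1, 0), 1, tolerance = 1e-8)
  expect_equal(laplace_derivative(ln, 2, 0) - 1, 0.25, tolerance = 1e-8)
})

test_that("gamma posterior expectation equals (theta+n)/(theta+Lambda)", {
  expect_equal(posterior_expectation(frailty_family("gamma", 2), 1, 1), 1)
  expect_equal(posterior_expectation(frailty_family("gamma", 1), 0, 1), 0.5)
  ## generic derivative-ratio route against the closed form on a grid
  for (th in c(0.5, 1, 4, 20)) {
    fam <- frailty_family("gamma", th)
    for (n in 0:6) for (cc in c(0.1, 1, 5)) {
      generic <- -laplace_derivative(fam, n + 1, cc) /
        laplace_derivative(fam, n, cc)
      expect_equal(generic, (th + n) / (th + cc), tolerance = 1e-10)
    }
  }
})

test_that("posterior expectation is monotone in history", {
  grid_c <- c(0.01, 0.1, 0.5, 1, 2, 5, 10)
  for (fam in list(frailty_family("gamma", 2),
                   frailty_family("inverse_gaussian", 2),
                   frailty_family("positive_stable", 0.8))) {
    for (n in 0:4) {
      v <- posterior_expectation(fam, n, grid_c)
      expect_true(all(diff(v) < 1e-12),
                  label = paste(fam$name, "nonincreasing in cumhaz"))
    }
    for (cc in grid_c) {
      v <- posterior_expectation(fam, 0:5, cc)
      expect_true(all(diff(v) > -1e-12),
                  label = paste(fam$name, "nondecreasing in n"))
    }
  }
  ## prior mean for mean-1 families at empty history
  expect_equal(posterior_expectation(frailty_family("gamma", 3), 0, 0), 1)
  expect_equal(posterior_expectation(frailty_family("inverse_gaussian", 3), 0, 0), 1)
})

test_that("marginal hazard ratio attenuates except for the positive stable", {
  expect_equal(marginal_hazard_ratio(frailty_family("gamma", 4), log(5), 1),
               25 / 9)
  for (fam in list(frailty_family("gamma", 2),
                   frailty_family("inverse_gaussian", 2),
                   frailty_family("lognormal", 4))) {
    expect_equal(marginal_hazard_ratio(fam, log(5), 0), 5, tolerance = 1e-7)
  }
  ## gamma: decreasing from exp(beta) toward 1
  v <- marginal_hazard_ratio(frailty_family("gamma", 2), log(5),
                             c(0, 0.5, 1, 2, 5, 20, 100))
  expect_true(all(diff(v) < 0))
  expect_lt(v[length(v)], 1.3)
  ## positive stable: constant at 5^b
  ps <- frailty_family("positive_stable", 1)
  expect_equal(marginal_hazard_ratio(ps, log(5), c(0.2, 1, 7)),
               rep(5^0.5, 3))
})

test_that("median concordance closed forms and limits", {
  expect_equal(median_concordance(frailty_family("gamma", 1)), 1 / 3)
  expect_equal(median_concordance(frailty_family("positive_stable", 0)), 0)
  expect_lt(abs(median_concordance(frailty_family("gamma", 1e6))), 1e-5)
  expect_error(median_concordance(frailty_family("lognormal", 4)),
               "not implemented")
})

test_that("median concordance matches a bivariate Monte Carlo oracle", {
  set.seed(2024)
  n <- 1e6
  cases <- list(
    list(fam = frailty_family("gamma", 1), z = stats::rgamma(n, 1, 1)),
    list(fam = frailty_family("inverse_gaussian", 2), z = rinvgauss1(n, 2)),
    list(fam = frailty_family("positive_stable", 1), z = rposstable(n, 0.5)))
  for (cs in cases) {
    m <- laplace_inverse(cs$fam, 0.5)      # marginal median: S(t) = L(t)
    t1 <- stats::rexp(n) / cs$z
    t2 <- stats::rexp(n) / cs$z
    kap_mc <- mean(sign((t1 - m) * (t2 - m)))
    se <- sqrt((1 - kap_mc^2) / n)
    expect_lt(abs(median_concordance(cs$fam) - kap_mc), 3 * se,
              label = cs$fam$name)
  }
})
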
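# nphfrailty

Shared frailty models and nonproportional-hazards diagnostics for
clustered and recurrent event data — and a simulation framework for the
question the two keep raising: *is an apparently time-dependent covariate
effect real, or is it unobserved heterogeneity in disguise?*

## The science

For clustered failures (subjects nested in clusters) or recurrent events
(episodes nested in subjects), the shared frailty model assumes
proportional hazards *conditional* on a positive random effect Z with
mean 1 shared within the cluster:

    lambda(t | Z, x) = Z * lambda0(t) * exp(x' beta)

Marginally — integrating Z out — the hazard ratio between covariate
groups is time-dependent whenever Z has finite variance, because
survivors are selected for low frailty.  A genuinely time-dependent
effect beta(t) produces the same marginal signature, so on small clusters
the frailty variance estimate and its test absorb nonproportionality that
has nothing to do with heterogeneity.

The package provides:

* **Laplace-transform calculus** for gamma, inverse Gaussian, positive
  stable and lognormal frailty (`laplace()`, `laplace_derivative()`,
  `posterior_expectation()`, `marginal_hazard_ratio()`,
  `median_concordance()`), parametrized by an association parameter
  `theta` with Var Z = 1/theta (positive stable: L(c) = exp(-c^b),
  b = 1/(1+theta));
* a **semiparametric shared frailty estimator** (`fit_frailty()`):
  profile EM over theta with an offset Breslow/Newton M-step, marginal
  likelihood via Laplace derivatives, the **boundary-mixture likelihood
  ratio test** of no frailty (p = ½ P(chi²₁ ≥ LRT), 5% critical value
  2.7055) and **profile-likelihood confidence intervals** for the frailty
  variance (`profile_ci_variance()`);
* the **diagnostics** evaluated alongside: a Commenges–Andersen-style
  heterogeneity score test from within-cluster martingale residuals
  (`ca_test()`, with both the classical asymptotic and an exact
  permutation-moment standardization) and the global scaled-Schoenfeld
  proportional hazards test with Kaplan–Meier time transform
  (`zph_test()`);
* a **scenario simulator** (`scenario()`, `resolve_scenario()`,
  `simulate_dataset()`): Weibull baselines anchored by Lambda0(50) = 0.8,
  effect beta(t) = log 5 + beta1 log t, lognormal or gamma frailty,
  clustered / clustered-common / recurrent layouts, and administrative
  censoring calibrated to remove 30% of events;
* a **replication driver** (`run_scenario()`, `run_grid()`) aggregating
  rejection fractions, variance estimates, CI coverage and median
  concordance over design cells, plus a worked analysis of the classic
  38-patient kidney-catheter recurrence data (`kidney_analysis()`).

## Worked example

Simulate 150 clusters of size 2 with **no frailty** but a strongly
time-declining covariate effect (beta(t) = log 5 − 0.41 log t), then ask
the three instruments what they see:

```r
library(nphfrailty)
rs  <- resolve_scenario(scenario("clustered", 2, 300, weibull_shape = 1,
                                 beta1_level = 2), seed = 1)
d   <- simulate_dataset(rs, seed = 2)
cox <- fit_cox(Surv(stop, status) ~ x + cluster(cluster_id), d)
zph_test(cox)
#> Proportional hazards test (scaled Schoenfeld, km transform)
#>   statistic: chisq = 20.73061
#>   df: 1
#>   p-value: 5.2864e-06
ca_test(cox)
#> Heterogeneity score test (martingale variance)
#>   statistic: z = 0.5528337
#>   p-value: 0.29019
fit_frailty(Surv(stop, status) ~ x + cluster(cluster_id), d, "gamma",
            ci_variance = TRUE)
#> Shared frailty model (gamma family, profile EM)
#>   frailty variance = 0.0737 (theta = 13.58)
#>   95% profile CI [0, 0.326] on the variance
#> Coefficients:
#>         x
#> 0.6824125
#> Marginal log likelihood -1234.8792; no-frailty -1235.0359
#> LRT of no frailty: stat 0.3135, p = 0.2878
```

The proportional hazards test correctly screams (p ≈ 5e-6); the
heterogeneity test and the frailty LRT stay quiet on this draw — but over
many replicates of this cell the gamma LRT rejects in roughly 12–15% of
datasets at the nominal 5% level, the spurious-evidence phenomenon the
simulator exists to quantify.  Note also the attenuated coefficient
(0.68 versus the conditional log 5 ≈ 1.61 at t = 1): the fitted marginal
effect averages the declining beta(t) over follow-up.

On real data:

```r
kidney_analysis(kidney_catheter_data())
```

reproduces the textbook sequence on the kidney-catheter data, including
the gamma frailty variance rising from 0.177 (no covariates) to about
0.39 after adjusting for sex — covariate adjustment *increasing* apparent
heterogeneity, the signature of confounded nonproportionality — while the
positive stable model, which preserves marginal proportionality, sees no
frailty at all.

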
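---
title: "Nonproportional hazards or unobserved heterogeneity? Methods behind nphfrailty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonproportional hazards or unobserved heterogeneity? Methods behind nphfrailty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nphfrailty)
```

## The problem

In clustered failure-time data (members of a family, repeated catheter
insertions in a patient) the shared frailty model assumes that, *given* an
unobserved positive random effect $Z$ common to the cluster, hazards are
proportional:

$$\lambda(t \mid Z, x) = Z\, \lambda_0(t)\, e^{x^\top\beta}.$$

Averaging over $Z$ destroys proportionality: survivors of a high-risk group
are increasingly selected for low frailty, so the *marginal* hazard ratio
between covariate groups shrinks over time whenever $Z$ has finite
variance.  The converse is the troublesome direction: a covariate whose
effect genuinely declines with time produces marginal data patterns that a
frailty model is happy to absorb as evidence of unobserved heterogeneity.
With large clusters the within-cluster correlation structure identifies the
frailty separately; with clusters of size two or three, or few recurrent
events per subject, the two explanations are close to confounded.  This
package provides the estimator, the tests and a purpose-built simulator to
study exactly that confounding.

## Laplace-transform calculus

All cluster-level quantities derive from the frailty Laplace transform
$L(c) = E\,e^{-cZ}$ and its derivatives.  Writing $N_i$ for the events
observed in cluster $i$ and $\Lambda_i = \sum_j \int Y_{ij} e^{x_{ij}^\top\beta}
\,d\Lambda_0$ for its accumulated conditional cumulative hazard,

* the posterior frailty mean is
  $E[Z_i \mid \mathcal{F}_{t^-}] = -L^{(N_i+1)}(\Lambda_i) / L^{(N_i)}(\Lambda_i)$,
* the cluster's marginal likelihood contribution is
  $(-1)^{N_i} L^{(N_i)}(\Lambda_i)$,
* the marginal hazard ratio between groups and the median concordance
  $\kappa = 4L(2L^{-1}(\tfrac12)) - 1$ (clusters of size two) are closed
  functionals of $L$.

Families are parametrized with mean 1 and variance $1/\theta$ (gamma,
inverse Gaussian, lognormal).  The positive stable family has
$L(c) = \exp(-c^b)$ with $b = 1/(1+\theta)$, so $\theta = 0$ is the
degenerate no-frailty case; it has no finite variance and is the unique
family preserving marginal proportionality (the marginal hazard ratio is
$e^{\beta b}$, constant in time).  If a different stable-scale convention
is ever preferred, only `ps_index()` changes.

Derivatives are generated through the Leibniz recursion for
$Q_n = (-1)^n L^{(n)}/L$,

$$Q_{n+1}(c) = \sum_{j=0}^{n} \binom{n}{j}\, a_{j+1}(c)\, Q_{n-j}(c),
\qquad a_m = (-1)^{m-1} h^{(m)},\ h = -\log L,$$

whose terms are *all nonnegative* because $h$ is a Bernstein function — no
cancellation, so the recursion is numerically stable.  Gamma and inverse
Gaussian also have closed forms (a Pochhammer ratio and Bessel-$K$
functions) used as fast paths and cross-checked against the recursion in
the tests.  Positive stable derivatives are supported to order 30, far
above the event counts of any simulated cluster; beyond that the package
raises an explicit error rather than approximating silently.  The
lognormal family (simulation and curve display only, never fitting) uses
adaptive quadrature on the Gaussian scale with relative tolerance `1e-10`.
$L^{-1}$ uses closed forms where available and otherwise Brent root search
on $[10^{-12}, 10^6]$ to absolute tolerance $10^{-10}$.

## Estimation: profile EM

`fit_frailty()` maximizes the semiparametric marginal likelihood

$$\ell(\theta, \beta, \Lambda_0) = \sum_i \log\!\big[(-1)^{N_i}
L^{(N_i)}_\theta(\Lambda_i)\big] + \sum_{\text{events}} \big[x^\top\beta +
\log \Delta\Lambda_0\big]$$

by profiling: for fixed $\theta$, an EM iteration alternates the posterior
means $\hat z_i$ (E-step) with a Breslow/Newton proportional hazards fit
taking $\log \hat z_i$ as an offset (M-step); the fixed point is the joint
maximizer over $(\beta, \Lambda_0)$ and the observed-data likelihood is
then evaluated directly.  The inner loop stops when the largest change in
$\hat z$ falls below `1e-6` (at most 200 sweeps; at most 3 damped Newton
steps per sweep, which keeps the generalized-EM ascent property — the
trace is tested to be nondecreasing).  The outer search maximizes over
$\log\theta$ on $[\log 10^{-4}, \log 10^8]$ (positive stable:
$[\log 10^{-4}, \log 10^2]$) by Brent's method with tolerance `5e-3`,
warm-starting each evaluation from the previous one.  A maximum within 1%
of the range end is flagged as a boundary solution; at the no-frailty end
the variance estimate is reported as 0.

The Cox machinery underneath (`fit_cox()`) is a vectorized Newton fit of
the Breslow partial likelihood on counting-process data with half-open
risk intervals $(\text{start}, \text{stop}]$, internal covariate centering
for conditioning, and step-halving on overshoot.  Monotone likelihood
(separation) is flagged, not thrown.  Breslow tie handling is used
throughout: simulated times are continuous, and on real data with
coarsened times the estimates are those of the Breslow convention.

### Testing no frailty, and confidence intervals

The null hypothesis of no frailty sits on the parameter-space boundary, so
the likelihood ratio statistic is referred to the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$: `p = 0.5 P(chi2_1 >= stat)`, with
5% critical value $2.7055$.  Negative statistics (a numerical artefact of
finite search tolerance near the boundary) are clipped to zero.

`profile_ci_variance()` inverts the profile likelihood in $\theta$.  Two
thresholds are meaningful and both are provided:

* `mixture = TRUE` (default) uses $2.7055$, so the interval's lower bound
  is 0 *exactly when* the mixture LRT does not reject at 5% — the two
  procedures agree by construction;
* `mixture = FALSE` uses the conventional $\chi^2_1$ 95% threshold
  $3.84$, the wider interval customary for interior parameters and the
  convention used by the established implementations of this model family.

The package treats the choice as a reporting convention, not a fitting
choice; `kidney_analysis()` reports the conventional interval alongside
the mixture-matched one.

## Diagnostics

**Heterogeneity (`ca_test()`).**  The score statistic of a frailty model
at zero variance on the independence working model is
$T = \sum_i (M_{i\cdot}^2 - N_i)$, with $M_{i\cdot}$ the summed martingale
residuals of cluster $i$.  The default standardization is the asymptotic
one: the Breslow plug-in makes the cluster residual a martingale integral
$\int dM_i - (R_i/S_0)\, d\bar M$, giving variance
$4\big[\sum_i \int H_i^2 \, d\Lambda_i - C^\top I^{-1} C\big]$ with $H$
the baseline-projection-centred residual path and $C$ the covariance with
the regression score.  The finite-sample downward shift of $T$ induced by
plug-in shrinkage is deliberately not corrected; the test is therefore
slightly conservative in very small clusters, consistent with the
published behaviour of this construction.  The alternative
`method = "permutation"` standardizes $T$ by its *exact* moments under
random reassignment of unit residuals to clusters (closed forms in the
residual power sums), which is exactly calibrated conditionally and agrees
with an explicit cluster-shuffle reference by construction; it is the
better-calibrated test on its own terms but not the classical one.  The
two genuinely differ on small samples — they are different tests, and both
are exposed.

**Proportional hazards (`zph_test()`).**  The global scaled-Schoenfeld
score test with the Kaplan-Meier time transform, delegated to
`survival::cox.zph()` — deliberately the stock implementation and default
transform, because that is what a practitioner's workflow applies.

## The scenario simulator

`scenario()` describes one design cell; `resolve_scenario()` derives every
constant:

* Weibull baseline with shape $\alpha \in \{0.8, 1, 2\}$ and scale fixed by
  $\Lambda_0(50) = 0.8$ (clustered) or $0.8j$ (recurrent, $j$ events per
  subject), so cells are comparable across shapes;
* covariate $x \sim \text{Bernoulli}(0.5)$, drawn per subject, per cluster
  (`clustered_common`), or per subject (`recurrent`);
* log-time-dependent effect $\beta(t) = \beta_0 + \beta_1 \log t$ with
  $\beta_0 = \log 5$; level 2 sets $\beta_1 = -\beta_0/\log 50$
  ($\approx -0.41$, the effect vanishes at the horizon), level 1 half that
  ($\approx -0.21$), level 0 proportional hazards.  The conditional event
  time distribution is then again Weibull with shape $\alpha + \beta_1 x$,
  which must stay positive, and sampling is by exact inversion — no
  numerical hazard inversion;
* frailty lognormal (or gamma, for recovery tests) with mean 1 and variance
  $\sigma^2 \in \{0, 0.25\}$; the lognormal log-scale parameters solve the
  moment equations $s = \log(1+\sigma^2)$, $\mu = -s/2$;
* administrative censoring at the 0.7 quantile of the *uncensored* event
  time distribution of the same cell, estimated once per cell from a
  calibration sample of $10^5$ subjects on a dedicated seed stream, giving
  30% censoring by construction.

**Recurrent events are truncated at the design event count.**  Each
subject's calendar-time process is generated from unit-exponential
increments of the conditional cumulative intensity and followed to the
$j$-th event or the censoring time, whichever comes first; censoring
calibration pools the uncensored event times (exactly $j$ per subject).
An alternative reading — an unbounded conditional Poisson process observed
on a fixed window — was implemented and compared during development: only
the truncated design reproduces the joint behaviour of the heterogeneity,
proportional-hazards and frailty-LRT statistics in the recurrent cells
(the unbounded version leaves essentially no between-subject event-count
signal once the window is calibrated, and the heterogeneity test collapses
to its nominal level).  Truncation also makes observed event counts
directly comparable to a cluster of size $j$: about $0.7j$ events per
subject at 30% censoring.

Replicate $r$ of a cell uses seed `seed + r`; grid cells derive their
seeds by hashing the cell configuration together with the master seed, so
any sub-grid reproduces the corresponding rows of the full grid and
results are independent of evaluation order.  The number of replications
per cell is a user parameter; the package's own acceptance runs use 500,
which puts a binomial standard error of about $0.01$–$0.022$ on a
rejection fraction.

### What the generator does and does not emulate

It emulates the structural features that drive the confounding: shared
multiplicative frailty, a smoothly attenuating covariate effect,
administrative censoring at a fixed calibrated time, and the three
clustering layouts.  It does not emulate covariate-dependent or random
censoring, cluster-size imbalance, tied or coarsened event times,
time-varying covariates, or competing risks.  A test passing on these
scenarios therefore says nothing about, for example, informative censoring
— on real data the diagnostics retain their usual caveats.

## Numerical and degenerate-input choices

* Clusters that never intersect an event-time risk set ($\Lambda_i = 0$,
  $N_i = 0$) contribute nothing to the likelihood; their posterior mean is
  set to the prior value 1 (for the positive stable family the posterior
  mean at $\Lambda = 0$ does not exist — the family has infinite mean —
  but such rows cannot influence the fit).
* Derivative order for the positive stable E-step equals the cluster event
  count; the order-30 cap exceeds anything the simulated designs produce.
* `optimize()` never evaluates the exact range ends; the no-frailty
  reference likelihood is computed from the plain Cox fit, and the LRT
  statistic is clipped at 0.
* Ties, if present in user data, follow the Breslow convention everywhere
  (risk sums, residuals, and the `cox.zph` call).

## Worked example

```{r example, eval = FALSE}
rs <- resolve_scenario(scenario("clustered", 2, 300, weibull_shape = 1,
                                beta1_level = 2), seed = 1)
d <- simulate_dataset(rs, seed = 2)
cox <- fit_cox(Surv(stop, status) ~ x + cluster(cluster_id), d)
zph_test(cox)        # marginal nonproportionality: usually rejected
ca_test(cox)         # heterogeneity: usually not
fit_frailty(Surv(stop, status) ~ x + cluster(cluster_id), d, "gamma")
```

The replication driver aggregates this over cells:

```{r grid, eval = FALSE}
cells <- list(scenario("clustered", 2, 300, beta1_level = 2),
              scenario("clustered", 10, 300, beta1_level = 2))
run_grid(cells, reps = 500, master_seed = 1)
```

## Known limitations

* Lognormal frailty is generation-only; fitting it would require numerical
  integration inside the E-step and is out of scope.
* No stratification, Efron ties, robust variances, or correlated (partly
  individual) frailty structures.
* Profile confidence intervals are likelihood-based only; no
  information-matrix standard errors for the frailty variance are
  reported, since the boundary makes them misleading exactly where the
  package is most used.
* The heterogeneity test's two standardizations disagree in very small
  samples; the documentation of `ca_test()` explains which to use when.
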
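---
title: "Modeling Medicaid churn and utilization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Medicaid churn and utilization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medchurn)
```

## The modeling problem

Short panel surveys observe each person's Medicaid enrollment and
health-care utilization over `T` interview rounds spanning about two
years.  Utilization outcomes (emergency-room visits, office visits,
inpatient discharges, prescription fills) are small non-negative counts
measured per round, and the exposure of interest — how many times the
person moved into or out of Medicaid — is a person-level summary of the
enrollment path.  Among people enrolled at least once, three groups are
distinguished: continuously enrolled (no transitions), a single entry or
exit, and multiple transitions ("churners").

Two statistical obstacles shape the design:

* **Correlated heterogeneity.**  People differ persistently in their
  propensity to use care, and those differences are correlated with
  observables such as employment and health histories — churners are
  systematically younger, healthier and more often employed than the
  continuously enrolled.  A plain random-effects estimator that assumes
  the individual effect is independent of the regressors is then
  inconsistent.
* **State dependence and initial conditions.**  Utilization may be
  persistent (this round's visits depend on last round's), and in a
  short panel the first observed outcome is not exogenous: it already
  reflects the unobserved effect.

## The three specifications

With `y_it` the count and `x_it` the regressor vector (transition-group
indicators, age at baseline, sex, marital status, race, education,
family size, current employment, current self-reported health,
normalized income, chronic-condition count, round fixed effects), the
conditional mean is

$$\mathrm{E}[y_{it} \mid x_{it}, c_i] = \exp(x_{it}'\beta + c_i).$$

* `static1` estimates this directly under a random-effects assumption.
* `static2` adds the within-person means of the time-varying covariates
  (employment and health) to the index — the Mundlak device.  The means
  proxy the part of `c_i` that is correlated with the observed
  histories, restoring consistency when the correlation runs through
  those histories.
* `dynamic3` adds `\rho\,h(y_{i,t-1})` for state dependence and
  `\xi_0\,h(y_{i1})` as the initial-conditions control (the Wooldridge
  device: conditioning on the first observation absorbs the part of the
  unobserved effect it reveals), and uses rounds `2..T`, so a panel with
  `N` persons contributes `N(T-1)` observations instead of `NT`.

`h` is any non-decreasing transform of the count.  The package default
is the identity — then `exp(\rho)` is the IRR per visit/fill of the
previous round, matching how such tables are usually read — with
`log1p` available for heavy-tailed outcomes and required for stable
*generation* of state-dependent data (see below).

## Likelihoods and mixing laws

The individual effect is integrated out of the product of Poisson
kernels person by person.  Two laws are implemented:

* **Gamma (default).**  A multiplicative effect `a_i` with mean 1 and
  variance `1/theta`.  The marginal likelihood has the closed form
  $$\ell_i = \sum_t \left[y_{it}\log\lambda_{it} - \log y_{it}!\right]
    + \log\Gamma(\theta + S_y) - \log\Gamma(\theta)
    + \theta\log\theta - (\theta + S_y)\log(\theta + S_\lambda),$$
  with `S_y` and `S_lambda` the person's count and rate totals.  This is
  the classical random-effects Poisson panel likelihood and is the
  default because it is exact, fast, and matches the conventional
  random-effects Poisson estimator of standard econometrics software.
* **Log-normal (sensitivity).**  An additive `N(0, sigma^2)` effect on
  the log scale.  The integral has no closed form; it is evaluated by
  *adaptive* Gauss–Hermite quadrature: for each person the integrand's
  mode is found by Newton steps (the log-integrand is strictly concave,
  so this always converges) and the rule is recentred and rescaled by
  the curvature.  Twenty nodes then give ~1e-9 accuracy uniformly over
  the σ range of interest, where a fixed 64–128-node rule centred at
  zero degrades to ~1e-3 for σ above 1.  The no-heterogeneity limits
  (`theta -> Inf`, `sigma = 0`) both reduce to the pooled Poisson
  likelihood and are tested.

Maximization is quasi-Newton (`nlminb`) on `(beta, log theta)` or
`(beta, log sigma)` — the log transform enforces positivity — with
analytic gradients for both families.  Starting values are the pooled
Poisson fit for `beta` and a method-of-moments variance estimate from
person-level count/rate ratios for the mixing parameter; with fixed
starting values and no randomness, fits are bit-for-bit reproducible.
Convergence is declared from the first-order condition (scaled gradient
norm below 1e-3) rather than the optimizer's return code, which can
report "false convergence" at a genuine optimum under the tight relative
tolerance (1e-10) we request.  Standard errors come from the inverse of
the observed information (finite differences of the analytic gradient at
the optimum); the mixing parameter's standard error is delta-method
through the log link.  Incidence rate ratios are `exp(beta)` with
delta-method standard errors, and the rank of the regressor matrix is
checked up front so collinear columns fail by name instead of producing
a silent near-singular Hessian.

## The synthetic-data generator

`sim_config()` / `generate_dataset()` emulate the structure of a
two-year MEPS-like panel with known truth.  Design, and what each piece
emulates:

* **Enrollment** is a first-order Markov chain
  (start-enrolled 0.747, stay-enrolled 0.929, stay-unenrolled 0.648 per
  round), with all-zero histories redrawn because the study population
  is Medicaid-ever.  These defaults were calibrated once, by exact
  enumeration of all `2^6` histories, so that at `T = 6` the
  no/single/multiple mix is about 53/30/17 percent — the group mix such
  surveys report.  `T = 6` is the default because it reproduces the
  37,482-observation layout of a 6,247-person panel; five-round usage is
  fully supported since `T` is a dataset property.
* **Employment and health** are persistent binary chains (persistence
  0.8) whose person-level rates differ by mover status: stayers 17.4 %
  employed / 57.2 % healthy, movers 47 % / 77.5 % in every round.  This
  person-level contrast — movers are different people, not just
  different while uninsured — is what descriptive tables show, and it is
  what makes the baseline random-effects estimator biased in the study
  below.
* **Income** is log-normal around a person-level location with an
  employment premium; estimation uses the income *ratio* (income over
  the grand person-round mean), which has grand mean exactly 1.
* **The individual effect** is drawn from the configured mixing law and
  multiplied by `exp(d_e * mean_employed + d_h * mean_healthy)` — the
  correlation device.  Defaults `d_h = -1.0`, `d_e = -0.25` take the
  magnitudes that fitted within-mean coefficients show in this
  literature: health history matters a lot, employment history little.
* **Outcomes** are Poisson draws with log-mean `x'b + log a_i`
  (+ state-dependence terms when configured).  The default truth
  vectors follow the direction and size of published static-model IRRs
  for the four outcomes, with intercepts calibrated so per-round means
  land at realistic levels (≈0.14 ER visits, ≈0.09 discharges, ≈2.7
  office visits, ≈6.9 fills).
* **Reproducibility.**  A master seed spawns one substream per component
  (enrollment, covariates, outcomes), so changing the outcome truth
  never perturbs the enrollment draws.  The realized per-person effects
  are returned in a truth record for diagnostics and are never visible
  to estimators.

What the generator does *not* emulate: survey weights and design
effects, panel overlap across calendar years, attrition and item
nonresponse, reporting error in enrollment, and directionality of
transitions (who moved *into* vs *out of* coverage).  Passing tests on
these synthetic panels therefore demonstrate the estimators' statistical
correctness under the stated laws, not robustness to those real-data
complications.

### Two initial-condition schemes for dynamic data

When state dependence is on, the round-1 count must come from somewhere:

* `"shared"` (default): the individual effect is drawn first and the
  round-1 count is a no-lag draw that *includes* it.  The first
  observation is then informative about the effect — the
  initial-conditions problem — and conditioning on it as a regressor is
  an approximation.  Under this scheme the fitted initial-condition
  coefficient is strongly positive, the qualitative signature the
  dynamic specification exists to capture.
* `"conditional"`: the round-1 count is drawn first (no individual
  effect) and the effect is then drawn with a loading `xi_0 * h(y_1)`.
  This is exactly the generative model the dynamic estimator assumes, so
  it is the right benchmark for parameter *recovery*: the estimator is
  correctly specified and should be (and is) unbiased.

The recovery study uses the conditional scheme; the shared scheme is
exercised for the qualitative initial-condition signature.

### Why the state-dependence study uses `h = log1p`

With a log link, identity feedback `exp(rho * y_{t-1})` is explosive
with positive probability: one unusually large draw raises the next
round's mean multiplicatively, which raises the next draw, and the
recursion escapes to infinity.  At realistic scale (3,000 persons, 200
replications) such escapes occur and the generator's divergence guard
(log-mean above 20 is an error, not a silent overflow) stops them.  The
parameter-recovery study therefore uses the bounded transform
`h(y) = log(1 + y)` in both generation and estimation; `rho` is then
persistence per log-unit of the prior count.  Identity remains the
default for *estimation* on real-style data, where no generation
recursion is involved.

## Descriptive tables

`summarize_by_group()` reproduces the usual two-table layout:
person-level covariates summarized per person, round-varying covariates
and utilization per person-round (so count means are per-round figures),
each transition group compared against the continuously enrolled.  The
tests are the unequal-variance (Welch) t for continuous variables and
the pooled two-proportion z for binaries, two-sided, without continuity
correction.  Published tables of this kind rarely name their tests, so
this choice is a documented package convention — agreement in kind with
any particular published table should not be read as agreement in
method.  No multiplicity adjustment is applied, and person-round
comparisons ignore within-person clustering; both mirror common
practice for descriptive tables and are stated here so nobody mistakes
those p-values for the inferential results.

## Numerical choices and degenerate inputs

* Tolerances: optimizer relative tolerance 1e-10, iteration cap 500;
  convergence judged by the scaled gradient norm (1e-3).
* Quadrature: 20 adaptive Gauss–Hermite nodes by default; the node count
  is exposed and node-doubling changes fitted log-likelihoods by ~1e-9.
* The simulated log-mean is capped at 20: beyond that the configuration
  is rejected with advice, never silently truncated.
* Empty panels are valid for I/O (header-only round trip); single-person
  groups report missing dispersion with a warning; all-zero outcomes
  make the dynamic frame collinear and fail by name; incomplete round
  sequences are a hard error unless dropping is requested explicitly.
* Counts up to at least 1e4 are handled stably in the log-pmf via
  `lgamma`.

## Problem sizes used by the shipped studies

The acceptance studies fix their scales as part of the study design: the
correlated-effects bias study uses 3,000 persons x 6 rounds x 200
replications per estimator; the dynamic recovery study the same scale;
oracle checks use 200 random small instances (T <= 6, counts <= 20);
test calibration uses 2,000 null datasets.  The package itself has no
size limits beyond memory; the full 6,247 x 6 default fits in well under
a minute per specification.

## Known limitations

* Only Poisson mixtures are implemented — no negative-binomial or
  zero-inflated variants, no GEE or fixed-effects Poisson, and no
  survey-weighted estimation.
* The Mundlak means are computed over all `T` rounds including round 1,
  also in the dynamic specification (the full history is the most
  informative proxy; an alternative restricted to rounds `2..T` would
  differ slightly).
* Age enters as baseline age; a time-varying age would be absorbed
  almost entirely by the round fixed effects in a two-year window.
* Robust (sandwich) standard errors are not provided; the reported
  standard errors are model-based observed-information ones.
* Directionality of transitions (entry vs exit) is deliberately out of
  scope; both are one "transition".
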
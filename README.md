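# medchurn

Random-effects Poisson panel models of Medicaid enrollment churn and
health-care utilization.

## The problem

Adults move into and out of Medicaid frequently — eligibility depends on
income, family composition and health, and re-enrollment is easy to miss.
Panel surveys such as the Medical Expenditure Panel Survey (MEPS) observe
the same people over five to six interview rounds spanning two years, with
per-round counts of emergency-room visits, office/outpatient visits,
inpatient discharges and prescription fills.  The question `medchurn`
addresses is whether *instability* of coverage — one, or more than one,
transition into or out of Medicaid over the window — is associated with
different utilization, after controlling for who the movers are.

The package is for health-services researchers and biostatisticians who
want that analysis as a tested, reproducible pipeline: schema-validated
panel input, derived-variable construction, the three standard model
specifications, descriptive group tables, and a synthetic-data generator
with known truth so every stage (and the estimators' statistical
properties) can be checked without any restricted data.

## The models

For person *i* in round *t*, a count outcome `y_it` is modeled as Poisson
with conditional mean

```
E[y_it | x_it, c_i] = exp(x_it' b + c_i)
```

where `x_it` holds the one-transition and multiple-transition indicators,
demographics, current employment and self-reported health, normalized
household income, chronic-condition count and round fixed effects, and
`c_i` is an unobserved individual effect.  Three nested specifications are
fit by maximum likelihood with the effect integrated out:

1. **static1** — the baseline random-effects model above;
2. **static2** — adds the within-person means of employment and health
   (the Mundlak / correlated-random-effects device), so `c_i` may be
   correlated with those observed histories;
3. **dynamic3** — adds `h(y_{i,t-1})` (state dependence) and `h(y_{i1})`
   (the Wooldridge initial-conditions control), estimated on rounds
   `2..T`.

Two mixing laws are available for `c_i`: a multiplicative unit-mean gamma
effect with variance `1/theta` (closed-form marginal likelihood, the
default) and an additive normal effect on the log scale (adaptive
Gauss–Hermite quadrature).  Estimates are reported as incidence rate
ratios, `IRR = exp(b)`, with observed-information standard errors.

## Worked example

```r
library(medchurn)

# a synthetic two-year panel: 800 people, 6 rounds, known truth
sim   <- generate_dataset(sim_config(n_persons = 800, seed = 42))
panel <- sim$panel

dplyr::count(transition_profiles(panel), group)
#>   group        n
#> 1 none       427
#> 2 single     232
#> 3 multiple   141

fits <- compare_specs(panel, "er_visits")
dplyr::filter(tidy(fits), term == "multi_transition")
#>   spec     term             estimate std.error statistic p.value   irr irr.se stars
#> 1 static1  multi_transition  -0.194     0.141      -1.38    0.167 0.823  0.116 ""
#> 2 static2  multi_transition  -0.0606    0.143      -0.423   0.672 0.941  0.135 ""
#> 3 dynamic3 multi_transition  -0.0414    0.152      -0.273   0.785 0.959  0.146 ""
```

Reading the output: the generator's true multiple-transition effect for
ER visits is +0.09 on the log scale (IRR ≈ 1.09).  The baseline
random-effects specification lands far below it (IRR 0.82) because the
individual effect is negatively loaded on employment and health
histories, which churners have more of; the correlated-random-effects
and dynamic specifications absorb that channel and move the estimate
toward the truth (0.94, 0.96 — within one standard error of 1.09).  At
800 people the estimates are noisy (the stars column is empty); the
test suite repeats this comparison at 3,000 persons over 200
replications, where the baseline specification's downward bias
(about −0.25) is unmistakable while the within-means estimator is
unbiased to within ±0.01.

```r
autoplot(fits)                 # IRR forest plot across specifications
summarize_by_group(panel)      # group descriptive table with p-values
run_analysis(sim_config(seed = 1), out_dir = "report")  # full bundle
```

A thin command-line wrapper with `simulate` / `fit` / `report` / `all`
subcommands is installed at `inst/cli/medchurn.R`.

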
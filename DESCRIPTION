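Package: medchurn
Title: Random-Effects Poisson Panel Models of Medicaid Enrollment Churn
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how instability of Medicaid enrollment
    (transitions into and out of coverage) relates to health-care
    utilization counts in short longitudinal surveys such as the Medical
    Expenditure Panel Survey.  Provides a validated long-format panel
    schema, derived-variable construction (transition counts and groups,
    within-individual Mundlak means, lagged and initial-condition
    outcomes, income normalization, round fixed effects), maximum
    likelihood estimation of static and dynamic random-effects Poisson
    models with gamma (closed form) or log-normal (Gauss-Hermite)
    individual effects, group descriptive tables with two-sample tests,
    incidence-rate-ratio regression tables, and a synthetic-data
    generator with known truth that emulates the round structure and
    enrollment churn of a two-year MEPS panel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
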
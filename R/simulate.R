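#' Default generating coefficients for the four utilization outcomes
#'
#' Log-scale coefficient vectors used by [sim_config()] as the truth of
#' the synthetic data-generating process.  The slope patterns follow the
#' direction and rough magnitude typically reported for adult Medicaid
#' populations (healthy and employed people use less care; chronic
#' conditions raise utilization; churners differ by outcome), and the
#' intercepts are set so per-round mean counts land near observed MEPS
#' magnitudes (about 0.14 emergency-room visits, 0.09 inpatient
#' discharges, 2-3 office visits and 4-9 prescription fills per round).
#'
#' @return A named list with one coefficient vector per outcome.
#' @export
default_truth <- function() {
  common <- function(intercept, one, multi, age, male, married, hs, white,
                     fam, emp, healthy, inc, chronic) {
    c(intercept = intercept, one_transition = one, multi_transition = multi,
      age = age, male = male, married = married, high_school = hs,
      white = white, family_size = fam, employed = emp, healthy = healthy,
      income_ratio = inc, chronic_count = chronic)
  }
  list(
    er_visits = common(-0.09, -0.02, 0.09, -0.013, -0.28, -0.05, -0.04,
                       -0.02, -0.10, -0.20, -0.70, 0.012, 0.23),
    outpatient_visits = common(1.37, -0.41, -0.17, 0.011, -0.25, -0.06,
                               0.29, 0.11, -0.024, -0.38, -0.13, 0.016,
                               0.064),
    inpatient_discharges = common(-1.23, 0.01, 0.21, -0.005, -0.40, 0.04,
                                  0.10, 0.15, -0.022, -0.69, -0.73, -0.01,
                                  0.27),
    rx_fills = common(1.52, -0.67, -0.52, 0.034, -0.14, 0.056, 0.19,
                      0.046, -0.066, -0.16, -0.14, -0.018, 0.031)
  )
}

#' Configuration of the synthetic MEPS-like data-generating process
#'
#' Bundles every quantity the generator needs: sample sizes, the
#' first-order Markov enrollment chain (calibrated by default so the
#' no/single/multiple transition mix is about 53/30/17 percent at six
#' rounds among the Medicaid-ever), persistent binary employment and
#' health chains whose person-level rates differ between the stably
#' enrolled and movers (producing the observed pattern that churners are
#' more often employed and healthier),
#' a log-normal income process, simple static covariate laws, the true
#' coefficient vectors, the individual-effect law and its correlation
#' with employment/health histories, and optional state dependence.
#'
#' @param n_persons Number of individuals (default 6247).
#' @param n_rounds Rounds per person (default 6).
#' @param seed Integer master seed; component substreams (enrollment,
#'   covariates, outcomes) are derived from it so that, e.g., changing
#'   the outcome truth never perturbs the enrollment draws.
#' @param enrollment List with `p_start_enrolled`, `p_stay_enrolled`,
#'   `p_stay_unenrolled`.
#' @param covariates List of covariate-law parameters (see defaults).
#' @param truth Named list of log-scale coefficient vectors, one per
#'   outcome; names must be model-frame column names.
#' @param mixing List with `family` (`"gamma"`, `"normal"`, or `"none"`)
#'   and `theta` (gamma precision) or `sigma` (normal sd).
#' @param correlation List with loadings `mean_employed`, `mean_healthy`
#'   linking the log individual effect to the within-person means.
#' @param state_dependence List with `rho` (coefficient on the
#'   transformed lagged count), `xi_init` (loading of the individual
#'   effect on the transformed initial count under the conditional
#'   scheme), `h_form` (`"identity"` or `"log1p"`), and `initial_scheme`
#'   (`"shared"`: the individual effect is drawn first and the round-1
#'   count comes from the no-lag model including it; `"conditional"`:
#'   the round-1 count is drawn first and the individual effect loads on
#'   it, which is the generative model the dynamic estimator assumes).
#' @param outcomes Outcomes to simulate (others are zero-filled).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_persons = 6247,
                       n_rounds = 6,
                       seed = 1,
                       enrollment = list(),
                       covariates = list(),
                       truth = default_truth(),
                       mixing = list(),
                       correlation = list(),
                       state_dependence = list(),
                       outcomes = outcome_names()) {
  cfg <- list(
    n_persons = n_persons,
    n_rounds = n_rounds,
    seed = seed,
    enrollment = modifyList(
      list(p_start_enrolled = 0.747, p_stay_enrolled = 0.929,
           p_stay_unenrolled = 0.648),
      enrollment
    ),
    covariates = modifyList(
      list(p_employed_stable = 0.174, p_employed_mover = 0.47,
           employed_persist = 0.80,
           p_healthy_stable = 0.572, p_healthy_mover = 0.775,
           healthy_persist = 0.80,
           income_meanlog = 10, income_sdlog_person = 0.7,
           income_sdlog_round = 0.25, income_employed_boost = 0.4,
           p_male = 0.30, p_married = 0.33, p_high_school = 0.48,
           p_white = 0.67, age_mean = 40, age_sd = 13,
           family_size_rate = 2.3, chronic_rate = 0.17),
      covariates
    ),
    truth = truth,
    mixing = modifyList(list(family = "gamma", theta = 2, sigma = 0.5),
                        mixing),
    correlation = modifyList(list(mean_employed = -0.25, mean_healthy = -1.0),
                             correlation),
    state_dependence = modifyList(
      list(rho = 0, xi_init = 0, h_form = "identity",
           initial_scheme = "shared"),
      state_dependence
    ),
    outcomes = outcomes
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(unlist(cfg$enrollment),
             cfg$covariates$p_employed_stable,
             cfg$covariates$p_employed_mover,
             cfg$covariates$employed_persist,
             cfg$covariates$p_healthy_stable,
             cfg$covariates$p_healthy_mover,
             cfg$covariates$healthy_persist,
             cfg$covariates$p_male, cfg$covariates$p_married,
             cfg$covariates$p_high_school, cfg$covariates$p_white)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities in the simulation config must lie in [0, 1].",
          class = "medchurn_config_error")
  }
  if (cfg$n_rounds < 2) {
    abort("`n_rounds` must be at least 2.", class = "medchurn_config_error")
  }
  if (cfg$n_persons < 1) {
    abort("`n_persons` must be positive.", class = "medchurn_config_error")
  }
  if (!cfg$mixing$family %in% c("gamma", "normal", "none")) {
    abort("`mixing$family` must be gamma, normal, or none.",
          class = "medchurn_config_error")
  }
  if (cfg$mixing$family == "gamma" && cfg$mixing$theta <= 0) {
    abort("`mixing$theta` must be positive.",
          class = "medchurn_config_error")
  }
  if (cfg$mixing$family == "normal" && cfg$mixing$sigma < 0) {
    abort("`mixing$sigma` must be non-negative.",
          class = "medchurn_config_error")
  }
  if (!cfg$state_dependence$initial_scheme %in% c("shared", "conditional")) {
    abort("`initial_scheme` must be 'shared' or 'conditional'.",
          class = "medchurn_config_error")
  }
  missing_truth <- setdiff(cfg$outcomes, names(cfg$truth))
  if (length(missing_truth) > 0) {
    abort(paste0("`truth` lacks coefficients for outcome(s): ",
                 paste(missing_truth, collapse = ", ")),
          class = "medchurn_config_error")
  }
  invisible(cfg)
}

#' Simulate Medicaid enrollment histories
#'
#' First-order Markov chain over rounds; persons whose whole history is
#' zero are redrawn, because the study population is defined as enrolled
#' in Medicaid during at least one round.
#'
#' @param config A [sim_config()].
#' @return An `n_persons x n_rounds` 0/1 matrix.
#' @export
simulate_enrollment <- function(config) {
  n <- config$n_persons
  T_n <- config$n_rounds
  e <- config$enrollment
  draw <- function(m) {
    out <- matrix(0L, m, T_n)
    out[, 1] <- rbinom(m, 1, e$p_start_enrolled)
    for (t in 2:T_n) {
      p_stay <- ifelse(out[, t - 1] == 1, e$p_stay_enrolled,
                       1 - e$p_stay_unenrolled)
      out[, t] <- rbinom(m, 1, p_stay)
    }
    out
  }
  enr <- draw(n)
  for (i in 1:100) {
    bad <- rowSums(enr) == 0
    if (!any(bad)) break
    enr[bad, ] <- draw(sum(bad))
  }
  if (any(rowSums(enr) == 0)) {
    abort("Could not draw Medicaid-ever enrollment histories; check chain probabilities.",
          class = "medchurn_config_error")
  }
  enr
}

persistent_chain <- function(n, T_n, p_person, persist) {
  out <- matrix(0L, n, T_n)
  out[, 1] <- rbinom(n, 1, p_person)
  for (t in 2:T_n) {
    keep <- rbinom(n, 1, persist)
    fresh <- rbinom(n, 1, p_person)
    out[, t] <- ifelse(keep == 1, out[, t - 1], fresh)
  }
  out
}

#' Simulate covariates given enrollment histories
#'
#' Employment and self-reported health follow persistent binary chains
#' whose person-level innovation probabilities differ between the
#' continuously enrolled and persons who move in or out of Medicaid at
#' least once: movers are markedly more often employed and healthier in
#' every round, matching the descriptive contrast between the stably
#' covered and churners.  Income is log-normal around a person-level
#' location with an employment premium; static covariates are drawn from
#' simple marginal laws.
#'
#' @param config A [sim_config()].
#' @param enrollment Matrix from [simulate_enrollment()].
#' @return List with `static` (tibble, one row per person) and matrices
#'   `employed`, `healthy`, `income`.
#' @export
simulate_covariates <- function(config, enrollment) {
  n <- config$n_persons
  T_n <- config$n_rounds
  cv <- config$covariates
  mover <- apply(enrollment, 1, function(b) any(diff(b) != 0))
  employed <- persistent_chain(
    n, T_n, ifelse(mover, cv$p_employed_mover, cv$p_employed_stable),
    cv$employed_persist
  )
  healthy <- persistent_chain(
    n, T_n, ifelse(mover, cv$p_healthy_mover, cv$p_healthy_stable),
    cv$healthy_persist
  )
  mu <- rnorm(n, cv$income_meanlog, cv$income_sdlog_person)
  income <- exp(matrix(mu, n, T_n) + cv$income_employed_boost * employed +
                  matrix(rnorm(n * T_n, 0, cv$income_sdlog_round), n, T_n))
  static <- tibble(
    person_id = sprintf("p%06d", seq_len(n)),
    age = pmin(64, pmax(18, round(rnorm(n, cv$age_mean, cv$age_sd)))),
    male = rbinom(n, 1, cv$p_male),
    married = rbinom(n, 1, cv$p_married),
    high_school = rbinom(n, 1, cv$p_high_school),
    white = rbinom(n, 1, cv$p_white),
    family_size = 1L + rpois(n, cv$family_size_rate),
    chronic_count = rpois(n, cv$chronic_rate)
  )
  list(static = static, employed = employed, healthy = healthy,
       income = income)
}

# per-round linear index matrix (n x T) from a named truth vector
truth_index <- function(beta, static, employed, healthy, income_ratio,
                        group, mean_emp, mean_hea, T_n) {
  n <- nrow(static)
  eta <- matrix(0, n, T_n)
  person_vals <- list(
    intercept = rep(1, n),
    one_transition = as.numeric(group == "single"),
    multi_transition = as.numeric(group == "multiple"),
    age = static$age, male = static$male, married = static$married,
    high_school = static$high_school, white = static$white,
    family_size = static$family_size, chronic_count = static$chronic_count,
    mean_employed = mean_emp, mean_healthy = mean_hea
  )
  round_vals <- list(employed = employed, healthy = healthy,
                     income_ratio = income_ratio)
  for (nm in names(beta)) {
    if (nm %in% names(person_vals)) {
      eta <- eta + beta[[nm]] * person_vals[[nm]]
    } else if (nm %in% names(round_vals)) {
      eta <- eta + beta[[nm]] * round_vals[[nm]]
    } else if (grepl("^round_[0-9]+$", nm)) {
      r <- as.integer(sub("round_", "", nm))
      if (r >= 1 && r <= T_n) eta[, r] <- eta[, r] + beta[[nm]]
    } else {
      abort(paste0("Unknown truth coefficient name `", nm, "`."),
            class = "medchurn_config_error")
    }
  }
  eta
}

#' Simulate count outcomes given enrollment and covariates
#'
#' Counts are Poisson with log-mean `x'beta + log(alpha_i)` plus, when
#' state dependence is on, `rho * h(previous count)`.  The individual
#' effect `alpha_i` is drawn from the configured mixing law and shifted
#' multiplicatively by the correlation device
#' `exp(delta_e * mean_employed + delta_h * mean_healthy)`, so unobserved
#' heterogeneity is correlated with the observed histories.  See
#' [sim_config()] for the two initial-condition schemes.
#'
#' @param config A [sim_config()].
#' @param enrollment Matrix from [simulate_enrollment()].
#' @param covariates List from [simulate_covariates()].
#' @return List with `counts` (named list of `n x T` matrices) and
#'   `effects` (named list of per-person effect vectors).
#' @export
simulate_outcomes <- function(config, enrollment, covariates) {
  n <- config$n_persons
  T_n <- config$n_rounds
  sdep <- config$state_dependence
  n_tr <- apply(enrollment, 1, function(b) sum(abs(diff(b))))
  group <- classify_group(n_tr)
  mean_emp <- rowMeans(covariates$employed)
  mean_hea <- rowMeans(covariates$healthy)
  income_ratio <- covariates$income / mean(covariates$income)

  draw_effect <- function() {
    base <- switch(config$mixing$family,
      gamma = rgamma(n, shape = config$mixing$theta,
                     rate = config$mixing$theta),
      normal = exp(rnorm(n, 0, config$mixing$sigma)),
      none = rep(1, n)
    )
    base * exp(config$correlation$mean_employed * mean_emp +
                 config$correlation$mean_healthy * mean_hea)
  }

  counts <- list()
  effects <- list()
  for (oc in config$outcomes) {
    beta <- config$truth[[oc]]
    eta <- truth_index(beta, covariates$static, covariates$employed,
                       covariates$healthy, income_ratio, group,
                       mean_emp, mean_hea, T_n)
    alpha <- draw_effect()
    y <- matrix(0L, n, T_n)
    dynamic <- sdep$rho != 0 || sdep$xi_init != 0
    if (dynamic && sdep$initial_scheme == "conditional") {
      check_logmean(eta[, 1])
      y[, 1] <- rpois(n, exp(eta[, 1]))
      alpha <- alpha * exp(sdep$xi_init * h_transform(y[, 1], sdep$h_form))
    } else {
      lm1 <- eta[, 1] + log(alpha)
      check_logmean(lm1)
      y[, 1] <- rpois(n, exp(lm1))
    }
    for (t in 2:T_n) {
      lm <- eta[, t] + log(alpha) +
        if (dynamic) sdep$rho * h_transform(y[, t - 1], sdep$h_form) else 0
      check_logmean(lm)
      y[, t] <- rpois(n, exp(lm))
    }
    counts[[oc]] <- y
    effects[[oc]] <- alpha
  }
  list(counts = counts, effects = effects)
}

check_logmean <- function(lm) {
  if (any(lm > 20)) {
    abort("Simulated log-mean exceeds 20; reduce coefficient magnitudes or state dependence.",
          class = "medchurn_config_error")
  }
}

#' Generate a complete synthetic panel with known truth
#'
#' Runs enrollment, covariate and outcome simulation under independent
#' substreams derived from the master seed, assembles a long-format panel
#' passing all schema invariants, and returns it with a truth record
#' (generating parameters plus realized per-person effects, for
#' diagnostics only - estimators never see it).
#'
#' @param config A [sim_config()].
#' @return A list of class `mc_sim` with elements `panel` (validated
#'   tibble) and `truth`.
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(n_persons = 25, seed = 42))
#' dim(sim$panel)
generate_dataset <- function(config) {
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  substreams <- sample.int(2147483646L, 3)

  set.seed(substreams[1])
  enrollment <- simulate_enrollment(config)
  set.seed(substreams[2])
  covariates <- simulate_covariates(config, enrollment)
  set.seed(substreams[3])
  outcomes <- simulate_outcomes(config, enrollment, covariates)

  n <- config$n_persons
  T_n <- config$n_rounds
  zero <- matrix(0L, n, T_n)
  get_counts <- function(oc) {
    if (oc %in% names(outcomes$counts)) outcomes$counts[[oc]] else zero
  }
  panel <- tibble(
    person_id = rep(covariates$static$person_id, each = T_n),
    round = rep(seq_len(T_n), n),
    medicaid = as.integer(t(enrollment)),
    employed = as.integer(t(covariates$employed)),
    healthy = as.integer(t(covariates$healthy)),
    income = as.double(t(covariates$income)),
    er_visits = as.integer(t(get_counts("er_visits"))),
    outpatient_visits = as.integer(t(get_counts("outpatient_visits"))),
    inpatient_discharges = as.integer(t(get_counts("inpatient_discharges"))),
    rx_fills = as.integer(t(get_counts("rx_fills"))),
    age = rep(covariates$static$age, each = T_n),
    male = rep(covariates$static$male, each = T_n),
    married = rep(covariates$static$married, each = T_n),
    high_school = rep(covariates$static$high_school, each = T_n),
    white = rep(covariates$static$white, each = T_n),
    family_size = rep(covariates$static$family_size, each = T_n),
    chronic_count = rep(covariates$static$chronic_count, each = T_n)
  )
  panel <- validate_panel(panel)
  structure(
    list(panel = panel,
         truth = list(config = config, effects = outcomes$effects)),
    class = "mc_sim"
  )
}
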
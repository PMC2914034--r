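#' Count Medicaid enrollment transitions in one enrollment history
#'
#' A transition is any adjacent-round change in the enrollment indicator,
#' i.e. the number of pairs `(t, t+1)` with differing enrollment.  The
#' analysis sample is defined as Medicaid-ever (enrolled in at least one
#' round); an all-zero history is therefore flagged with a warning, not an
#' error.
#'
#' @param enrollment Binary vector (0/1) of per-round enrollment, ordered
#'   by round.
#' @return Integer number of adjacent-round changes, in `0..(T-1)`.
#' @export
#' @examples
#' count_transitions(c(0, 0, 1, 1, 1)) # entered once
#' count_transitions(c(1, 0, 1, 0, 1)) # churner
count_transitions <- function(enrollment) {
  if (length(enrollment) < 1) {
    abort("`enrollment` must have at least one round.",
          class = "medchurn_validation_error")
  }
  if (!is.numeric(enrollment) || !all(enrollment %in% c(0, 1))) {
    abort("`enrollment` must contain only 0 and 1.",
          class = "medchurn_validation_error")
  }
  if (all(enrollment == 0)) {
    warn("Enrollment history is all zero; the sample is Medicaid-ever by construction.")
  }
  sum(abs(diff(enrollment)))
}

#' Classify a transition count into enrollment-stability groups
#'
#' Zero transitions means continuous Medicaid coverage over the whole
#' observation window; one transition means a single entry or exit;
#' more than one marks the unstably insured ("churners").
#'
#' @param n Vector of non-negative transition counts.
#' @return A factor with levels `none`, `single`, `multiple`.
#' @export
classify_group <- function(n) {
  if (any(!is.finite(n) | n < 0 | n != round(n))) {
    abort("Transition counts must be non-negative integers.",
          class = "medchurn_validation_error")
  }
  factor(
    ifelse(n == 0, "none", ifelse(n == 1, "single", "multiple")),
    levels = c("none", "single", "multiple")
  )
}

#' Per-person transition profiles
#'
#' @param panel A validated panel tibble.
#' @return A tibble with one row per person: `person_id`, `n_transitions`,
#'   and the derived `group` factor (`none` / `single` / `multiple`).
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(n_persons = 50, seed = 1))
#' dplyr::count(transition_profiles(sim$panel), group)
transition_profiles <- function(panel) {
  panel |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      n_transitions = sum(abs(diff(.data$medicaid[order(.data$round)]))),
      .groups = "drop"
    ) |>
    dplyr::mutate(group = classify_group(.data$n_transitions))
}

#' Within-person means of time-varying covariates
#'
#' Computes the arithmetic mean over all rounds of each requested
#' round-varying variable, one value per person.  These within-individual
#' means are the Mundlak device: adding them to a random-effects
#' specification lets the individual effect correlate with the observed
#' histories (here employment and self-reported health) without
#' inconsistency.
#'
#' @param panel A validated panel tibble.
#' @param variables Names of round-varying columns; default employment and
#'   health status.
#' @return A tibble with `person_id` and one `mean_<variable>` column per
#'   requested variable.
#' @export
within_means <- function(panel, variables = c("employed", "healthy")) {
  unknown <- setdiff(variables, names(panel))
  if (length(unknown) > 0) {
    abort(paste0("Unknown variable(s): ", paste(unknown, collapse = ", ")),
          class = "medchurn_validation_error")
  }
  panel |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(variables), mean, .names = "mean_{.col}"),
      .groups = "drop"
    )
}

#' Normalize income by the grand sample mean
#'
#' Divides each person-round income by the mean income over all
#' person-rounds in the dataset, so the resulting `income_ratio` has grand
#' mean exactly 1 and is interpretable as "times the average income of the
#' sample".
#'
#' @param panel A validated panel tibble.
#' @return The panel with an added `income_ratio` column.
#' @export
normalize_income <- function(panel) {
  grand_mean <- mean(panel$income)
  if (!is.finite(grand_mean) || grand_mean <= 0) {
    abort("Grand mean income must be positive to form income ratios.",
          class = "medchurn_validation_error")
  }
  dplyr::mutate(panel, income_ratio = .data$income / grand_mean)
}

#' Lagged and initial values of an outcome
#'
#' For each person, the lag at round `t` is the outcome at round `t - 1`
#' (undefined, `NA`, at round 1) and the initial value is the round-1
#' outcome repeated across rounds.  The dynamic specification uses both:
#' the lag captures state dependence and the initial value conditions on
#' the (non-exogenous) first observation, so rounds `2..T` are the usable
#' estimation sample.
#'
#' @param panel A validated panel tibble.
#' @param outcome Name of a count outcome column.
#' @return The panel with added `lag_<outcome>` and `init_<outcome>`
#'   columns.
#' @export
lag_and_initial <- function(panel, outcome) {
  if (!outcome %in% names(panel)) {
    abort(paste0("Unknown outcome `", outcome, "`."),
          class = "medchurn_validation_error")
  }
  if (n_rounds(panel) < 2) {
    abort("Lag structure requires at least two rounds.",
          class = "medchurn_validation_error")
  }
  panel |>
    dplyr::group_by(.data$person_id) |>
    dplyr::arrange(.data$round, .by_group = TRUE) |>
    dplyr::mutate(
      "lag_{outcome}" := dplyr::lag(.data[[outcome]]),
      "init_{outcome}" := .data[[outcome]][1]
    ) |>
    dplyr::ungroup()
}

h_transform <- function(x, h_form) {
  switch(h_form,
    identity = x,
    log1p = log1p(x),
    abort(paste0("Unknown h form `", h_form, "`."),
          class = "medchurn_validation_error")
  )
}

#' Assemble the regression frame for one specification of one outcome
#'
#' Builds the outcome vector and named regressor matrix for the three
#' model specifications:
#'
#' * `static1` — baseline random-effects regressors: intercept, the
#'   one-transition and multiple-transition indicators, age at baseline,
#'   male, married, high-school completion, white, family size, current
#'   employment, current self-reported health, income ratio, number of
#'   chronic conditions, and round fixed effects (first modeled round is
#'   the reference).
#' * `static2` — `static1` plus the within-person means of employment and
#'   health status (correlated-random-effects augmentation).
#' * `dynamic3` — `static2` plus `h(lagged outcome)` and
#'   `h(initial outcome)`, with rows restricted to rounds `2..T`.
#'
#' `h` is a non-decreasing transform of the count, by default the identity
#' (one coefficient per visit/fill of the prior or initial round);
#' `"log1p"` is available for heavy-tailed outcomes.
#'
#' @param panel A validated panel tibble.
#' @param outcome One of `er_visits`, `outpatient_visits`,
#'   `inpatient_discharges`, `rx_fills` (or any count column).
#' @param spec `"static1"`, `"static2"`, or `"dynamic3"`.
#' @param h_form Transform of lagged/initial counts for `dynamic3`:
#'   `"identity"` (default) or `"log1p"`.
#' @return A `mc_frame` tibble with columns `person_id`, `round`, `.y`
#'   (the outcome) followed by the regressors in fixed order; attributes
#'   `outcome`, `spec`, and `h_form` record the configuration.
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(n_persons = 30, seed = 2))
#' fr <- build_model_frame(sim$panel, "er_visits", "dynamic3")
#' nrow(fr) # 30 * (T - 1)
build_model_frame <- function(panel, outcome,
                              spec = c("static1", "static2", "dynamic3"),
                              h_form = c("identity", "log1p")) {
  spec <- match.arg(spec)
  h_form <- match.arg(h_form)
  if (!outcome %in% names(panel)) {
    abort(paste0("Unknown outcome `", outcome, "`."),
          class = "medchurn_validation_error")
  }
  T_n <- n_rounds(panel)
  if (spec == "dynamic3" && T_n < 2) {
    abort("The dynamic specification requires at least two rounds.",
          class = "medchurn_validation_error")
  }

  prof <- transition_profiles(panel)
  wm <- within_means(panel)
  df <- panel |>
    normalize_income() |>
    dplyr::left_join(prof, by = "person_id") |>
    dplyr::left_join(wm, by = "person_id")

  if (spec == "dynamic3") {
    df <- lag_and_initial(df, outcome)
    df <- df[df$round >= 2, , drop = FALSE]
  }

  first_round <- min(df$round)
  out <- tibble(
    person_id = df$person_id,
    round = df$round,
    .y = as.integer(df[[outcome]]),
    intercept = 1,
    one_transition = as.integer(df$group == "single"),
    multi_transition = as.integer(df$group == "multiple"),
    age = df$age,
    male = df$male,
    married = df$married,
    high_school = df$high_school,
    white = df$white,
    family_size = df$family_size,
    employed = df$employed,
    healthy = df$healthy,
    income_ratio = df$income_ratio,
    chronic_count = df$chronic_count
  )
  if (spec %in% c("static2", "dynamic3")) {
    out$mean_employed <- df$mean_employed
    out$mean_healthy <- df$mean_healthy
  }
  if (spec == "dynamic3") {
    out[[paste0("lag_", outcome)]] <-
      h_transform(df[[paste0("lag_", outcome)]], h_form)
    out[[paste0("init_", outcome)]] <-
      h_transform(df[[paste0("init_", outcome)]], h_form)
  }
  for (r in setdiff(sort(unique(df$round)), first_round)) {
    out[[paste0("round_", r)]] <- as.integer(df$round == r)
  }
  out <- dplyr::arrange(out, .data$person_id, .data$round)
  structure(out,
            class = c("mc_frame", class(out)),
            outcome = outcome, spec = spec, h_form = h_form)
}

#' Extract the regressor matrix of a model frame
#'
#' @param frame A `mc_frame` from [build_model_frame()].
#' @return Named numeric matrix of regressors (everything after the
#'   bookkeeping columns).
#' @export
frame_matrix <- function(frame) {
  keep <- setdiff(names(frame), c("person_id", "round", ".y"))
  as.matrix(frame[keep])
}
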
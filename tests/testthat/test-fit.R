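test_that("intercept-only pooled fit recovers log of the mean count", {
  sim <- generate_dataset(tiny_config(n_persons = 80, seed = 4))
  fr <- build_model_frame(sim$panel, "outpatient_visits", "static1")
  fr_int <- fr[c("person_id", "round", ".y", "intercept")]
  for (a in c("outcome", "spec", "h_form")) {
    attr(fr_int, a) <- attr(fr, a)
  }
  fit <- fit_re_poisson(fr_int, mixing = "pooled")
  expect_equal(unname(fit$coefficients["intercept"]), log(mean(fr$.y)),
               tolerance = 1e-7)
})

test_that("fitting is deterministic: identical frames give identical results", {
  sim <- generate_dataset(tiny_config(n_persons = 60, seed = 6))
  fr <- build_model_frame(sim$panel, "outpatient_visits", "static1")
  f1 <- fit_re_poisson(fr)
  f2 <- fit_re_poisson(fr)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$std_errors, f2$std_errors)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("IRRs are exp(coefficients) and tidy/glance expose the fit", {
  sim <- generate_dataset(tiny_config(n_persons = 60, seed = 8))
  fit <- fit_re_poisson(build_model_frame(sim$panel, "rx_fills", "static2"))
  expect_identical(fit$irr, exp(fit$coefficients))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "irr", "stars")
                  %in% names(td)))
  expect_equal(td$irr, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 360)
  expect_equal(gl$n_persons, 60)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the within-means specification never fits worse than the baseline", {
  for (seed in c(31, 32, 33)) {
    sim <- generate_dataset(tiny_config(n_persons = 120, seed = seed))
    f1 <- fit_re_poisson(
      build_model_frame(sim$panel, "outpatient_visits", "static1"),
      se = FALSE)
    f2 <- fit_re_poisson(
      build_model_frame(sim$panel, "outpatient_visits", "static2"),
      se = FALSE)
    expect_gte(f2$loglik, f1$loglik - 1e-6)
  }
})

test_that("rescaling a regressor rescales its coefficient and preserves the likelihood", {
  sim <- generate_dataset(tiny_config(n_persons = 80, seed = 12))
  fr <- build_model_frame(sim$panel, "outpatient_visits", "static1")
  fit <- fit_re_poisson(fr, se = FALSE)
  fr10 <- fr
  fr10$income_ratio <- fr10$income_ratio * 10
  fit10 <- fit_re_poisson(fr10, se = FALSE)
  expect_equal(unname(fit10$coefficients["income_ratio"]) * 10,
               unname(fit$coefficients["income_ratio"]),
               tolerance = 1e-4)
  expect_equal(fit10$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("rank-deficient frames fail loudly, naming the collinear column", {
  sim <- generate_dataset(tiny_config(n_persons = 40, seed = 13))
  fr <- build_model_frame(sim$panel, "er_visits", "static1")
  fr$employed_copy <- fr$employed
  expect_error(fit_re_poisson(fr), "employed_copy",
               class = "medchurn_rank_error")
})

test_that("gamma-mixed ML recovers generating coefficients within 3.5 standard errors", {
  cfg <- tiny_config(n_persons = 2000, seed = 101, n_rounds = 5,
                     outcomes = "outpatient_visits")
  sim <- generate_dataset(cfg)
  fit <- fit_re_poisson(
    build_model_frame(sim$panel, "outpatient_visits", "static2"))
  truth <- cfg$truth$outpatient_visits
  for (term in c("multi_transition", "employed", "healthy",
                 "chronic_count", "income_ratio")) {
    expect_lt(abs(fit$coefficients[term] - truth[term]),
              3.5 * fit$std_errors[term])
  }
  # theta is recovered on the same scale as the generator
  expect_lt(abs(fit$mixing_estimate - cfg$mixing$theta),
            3.5 * fit$mixing_se)
})

test_that("normal-mixing fit agrees with an independent adaptive-quadrature GLMM fit", {
  skip_if_not_installed("lme4")
  cfg <- tiny_config(n_persons = 400, seed = 55,
                     mixing = list(family = "normal", sigma = 0.5),
                     outcomes = "outpatient_visits")
  sim <- generate_dataset(cfg)
  fr <- build_model_frame(sim$panel, "outpatient_visits", "static1")
  fit <- fit_re_poisson(fr, mixing = "normal", se = FALSE)

  d <- data.frame(y = fr$.y, pid = fr$person_id,
                  scale(frame_matrix(fr)[, -1]))
  form <- stats::as.formula(paste(
    "y ~", paste(setdiff(names(d), c("y", "pid")), collapse = " + "),
    "+ (1 | pid)"))
  ref <- suppressWarnings(
    lme4::glmer(form, data = d, family = stats::poisson, nAGQ = 25))
  expect_equal(unname(fit$mixing_estimate),
               unname(sqrt(unlist(lme4::VarCorr(ref)))),
               tolerance = 0.02)
  # slopes on standardized regressors should agree closely
  sds <- attr(scale(frame_matrix(fr)[, -1]), "scaled:scale")
  ours <- fit$coefficients[-1] * sds
  theirs <- lme4::fixef(ref)[-1]
  expect_equal(unname(ours[c("employed", "healthy", "chronic_count")]),
               unname(theirs[c("employed", "healthy", "chronic_count")]),
               tolerance = 0.02)
})

test_that("compare_specs returns the three-specification set with the dynamic extras", {
  sim <- generate_dataset(tiny_config(n_persons = 100, seed = 77))
  fits <- compare_specs(sim$panel, "er_visits", se = FALSE)
  expect_named(fits, c("static1", "static2", "dynamic3"))
  expect_true(all(c("lag_er_visits", "init_er_visits") %in%
                    names(fits$dynamic3$coefficients)))
  expect_false(any(c("lag_er_visits", "init_er_visits") %in%
                     names(fits$static2$coefficients)))
  expect_equal(fits$dynamic3$n_obs, 100 * 5)
  td <- tidy(fits)
  expect_true(all(c("static1", "static2", "dynamic3") %in% td$spec))
})
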
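test_that("generation is deterministic under a seed and varies across seeds", {
  a <- generate_dataset(tiny_config(n_persons = 40, seed = 7))
  b <- generate_dataset(tiny_config(n_persons = 40, seed = 7))
  c_ <- generate_dataset(tiny_config(n_persons = 40, seed = 8))
  expect_identical(a$panel, b$panel)
  expect_false(identical(a$panel, c_$panel))
})

test_that("generated panels satisfy the schema invariants by construction", {
  sim <- generate_dataset(tiny_config(n_persons = 50, seed = 19))
  expect_silent(validate_panel(sim$panel))
  expect_equal(nrow(sim$panel), 50 * 6)
})

test_that("an absorbing enrollment chain produces no transitions", {
  cfg <- tiny_config(n_persons = 50, seed = 1,
                     enrollment = list(p_start_enrolled = 1,
                                       p_stay_enrolled = 1))
  sim <- generate_dataset(cfg)
  prof <- transition_profiles(sim$panel)
  expect_true(all(prof$n_transitions == 0))
})

test_that("a memoryless half-half chain averages 2.5 transitions over six rounds", {
  cfg <- sim_config(n_persons = 4000, seed = 2,
                    enrollment = list(p_start_enrolled = 0.5,
                                      p_stay_enrolled = 0.5,
                                      p_stay_unenrolled = 0.5),
                    outcomes = "er_visits")
  set.seed(cfg$seed)
  enr <- simulate_enrollment(cfg)
  n_tr <- apply(enr, 1, function(b) sum(abs(diff(b))))
  # conditioning on Medicaid-ever tilts the Bernoulli(1/2) mean up by
  # 2.5/63, so allow a little more than Monte-Carlo slack around 2.5
  expect_equal(mean(n_tr), 2.5, tolerance = 0.1)
})

test_that("the packaged default chain reproduces the target group mix", {
  cfg <- sim_config(n_persons = 10000, seed = 3, outcomes = "er_visits")
  sim <- generate_dataset(cfg)
  shares <- 100 * prop.table(table(transition_profiles(sim$panel)$group))
  expect_lt(abs(shares[["none"]] - 53.2), 3)
  expect_lt(abs(shares[["single"]] - 30.1), 3)
  expect_lt(abs(shares[["multiple"]] - 16.7), 3)
})

test_that("covariate chains freeze under full persistence and mix under none", {
  cfg1 <- tiny_config(n_persons = 60, seed = 5,
                      covariates = list(employed_persist = 1,
                                        healthy_persist = 1))
  sim1 <- generate_dataset(cfg1)
  per_person <- tapply(sim1$panel$employed, sim1$panel$person_id,
                       function(x) length(unique(x)))
  expect_true(all(per_person == 1))

  cfg2 <- sim_config(n_persons = 3000, seed = 6, outcomes = "er_visits",
                     covariates = list(p_employed_stable = 0.35,
                                       p_employed_mover = 0.35,
                                       employed_persist = 0.5))
  sim2 <- generate_dataset(cfg2)
  expect_lt(abs(mean(sim2$panel$employed) - 0.35), 0.02)
})

test_that("a null generating process yields i.i.d. Poisson(1) counts", {
  null_truth <- list(er_visits = c(intercept = 0))
  cfg <- sim_config(n_persons = 5000, seed = 10, outcomes = "er_visits",
                    truth = null_truth,
                    mixing = list(family = "none"),
                    correlation = list(mean_employed = 0, mean_healthy = 0))
  sim <- generate_dataset(cfg)
  y <- sim$panel$er_visits
  expect_equal(mean(y), 1, tolerance = 0.02)
  expect_equal(var(y) / mean(y), 1, tolerance = 0.05)
})

test_that("gamma mixing over a null index makes person totals overdispersed", {
  null_truth <- list(er_visits = c(intercept = 0))
  cfg <- sim_config(n_persons = 4000, seed = 11, outcomes = "er_visits",
                    truth = null_truth,
                    mixing = list(family = "gamma", theta = 1),
                    correlation = list(mean_employed = 0, mean_healthy = 0))
  sim <- generate_dataset(cfg)
  totals <- tapply(sim$panel$er_visits, sim$panel$person_id, sum)
  expect_gt(var(totals) / mean(totals), 1.5)
})

test_that("state dependence induces positive lag-1 autocorrelation", {
  null_truth <- list(er_visits = c(intercept = 0))
  base <- list(truth = null_truth, outcomes = "er_visits",
               mixing = list(family = "none"),
               correlation = list(mean_employed = 0, mean_healthy = 0))
  # bounded feedback (h = log1p) so the recursion cannot run away
  cfg_rho <- do.call(sim_config, c(
    list(n_persons = 4000, seed = 12,
         state_dependence = list(rho = 0.3, h_form = "log1p")), base))
  sim <- generate_dataset(cfg_rho)
  wide <- matrix(sim$panel$er_visits, nrow = 6)
  ac <- cor(as.vector(wide[-6, ]), as.vector(wide[-1, ]))
  expect_gt(ac, 0.1)
})

test_that("explosive configurations are refused with guidance", {
  cfg <- tiny_config(n_persons = 20, seed = 13,
                     truth = list(er_visits = c(intercept = 25)),
                     outcomes = "er_visits")
  expect_error(generate_dataset(cfg), "log-mean",
               class = "medchurn_config_error")
})

test_that("default dimensions reproduce the MEPS-like 6247 x 6 layout", {
  cfg <- sim_config(seed = 14, outcomes = "er_visits")
  sim <- generate_dataset(cfg)
  expect_equal(n_persons(sim$panel), 6247)
  expect_equal(nrow(sim$panel), 37482)
  f3 <- build_model_frame(sim$panel, "er_visits", "dynamic3")
  expect_equal(nrow(f3), 31235)
})

test_that("a two-round panel yields dynamic frames with one row per person", {
  cfg <- tiny_config(n_persons = 30, seed = 15, n_rounds = 2)
  sim <- generate_dataset(cfg)
  f3 <- build_model_frame(sim$panel, "er_visits", "dynamic3")
  expect_equal(nrow(f3), 30)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(enrollment = list(p_start_enrolled = 1.4)),
               class = "medchurn_config_error")
  expect_error(sim_config(n_rounds = 1), class = "medchurn_config_error")
  expect_error(sim_config(mixing = list(family = "cauchy")),
               class = "medchurn_config_error")
  expect_error(sim_config(outcomes = "er_visits", truth = list()),
               class = "medchurn_config_error")
})
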
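test_that("count_transitions counts adjacent enrollment changes", {
  expect_equal(count_transitions(c(1, 1, 1, 1, 1)), 0)
  expect_equal(count_transitions(c(0, 0, 1, 1, 1)), 1)
  expect_equal(count_transitions(c(1, 0, 1, 0, 1)), 4)
  expect_warning(count_transitions(c(0, 0, 0)), "Medicaid-ever")
  expect_error(count_transitions(c(1, 2, 0)),
               class = "medchurn_validation_error")
  expect_error(count_transitions(numeric(0)),
               class = "medchurn_validation_error")
})

test_that("classify_group maps counts to the three stability groups", {
  expect_equal(as.character(classify_group(c(0, 1, 2, 3, 5))),
               c("none", "single", "multiple", "multiple", "multiple"))
  expect_equal(levels(classify_group(0)), c("none", "single", "multiple"))
  expect_error(classify_group(-1), class = "medchurn_validation_error")
})

test_that("transition counting and grouping agree with brute force over all length-6 histories", {
  grids <- as.matrix(expand.grid(rep(list(0:1), 6)))
  for (i in seq_len(nrow(grids))) {
    b <- grids[i, ]
    n_oracle <- oracle_count_transitions(b)
    n_pkg <- if (all(b == 0)) {
      suppressWarnings(count_transitions(b))
    } else {
      count_transitions(b)
    }
    expect_identical(as.integer(n_pkg), as.integer(n_oracle))
    g <- classify_group(n_pkg)
    expect_identical(
      as.character(g),
      if (n_oracle == 0) "none" else if (n_oracle == 1) "single" else "multiple"
    )
  }
})

test_that("within_means averages each person's rounds", {
  p <- make_panel(list(c(1, 1, 0, 0, 0)))
  p$employed <- c(1L, 0L, 1L, 0L, 0L)
  p$healthy <- rep(1L, 5)
  wm <- within_means(p)
  expect_equal(wm$mean_employed, 0.4)
  expect_equal(wm$mean_healthy, 1.0)
  expect_error(within_means(p, "no_such_column"),
               class = "medchurn_validation_error")

  set.seed(3)
  for (i in 1:50) {
    seqs <- rbinom(6, 1, 0.5)
    p1 <- make_panel(list(rep(1, 6)))
    p1$employed <- as.integer(seqs)
    expect_equal(within_means(p1)$mean_employed, sum(seqs) / 6)
  }
})

test_that("normalize_income rescales to grand mean one", {
  p <- make_panel(list(c(1, 1, 1)), income = list(c(10, 20, 30)))
  out <- normalize_income(p)
  expect_equal(out$income_ratio, c(0.5, 1.0, 1.5))

  p$income <- rep(7, 3)
  expect_equal(normalize_income(p)$income_ratio, rep(1, 3))

  sim <- generate_dataset(tiny_config(n_persons = 40, seed = 9))
  expect_equal(mean(normalize_income(sim$panel)$income_ratio), 1,
               tolerance = 1e-12)

  p$income <- rep(0, 3)
  expect_error(normalize_income(p), class = "medchurn_validation_error")
})

test_that("lag_and_initial shifts by one round and pins the round-1 value", {
  p <- make_panel(list(c(1, 1, 1, 1, 1)),
                  er_visits = list(c(2L, 0L, 1L, 3L, 0L)))
  out <- lag_and_initial(p, "er_visits")
  expect_equal(out$lag_er_visits, c(NA, 2, 0, 1, 3))
  expect_equal(out$init_er_visits, rep(2L, 5))

  p0 <- make_panel(list(c(1, 1, 1)))
  out0 <- lag_and_initial(p0, "er_visits")
  expect_equal(out0$lag_er_visits[-1], c(0, 0))
  expect_equal(out0$init_er_visits, rep(0L, 3))

  set.seed(5)
  for (i in 1:20) {
    y <- rpois(6, 2)
    p1 <- make_panel(list(rep(1, 6)), er_visits = list(as.integer(y)))
    lag <- lag_and_initial(p1, "er_visits")$lag_er_visits
    for (t in 2:6) expect_equal(lag[t], y[t - 1])
  }

  p2 <- make_panel(list(1))
  expect_error(lag_and_initial(p2, "er_visits"),
               class = "medchurn_validation_error")
  expect_error(lag_and_initial(p, "nope"),
               class = "medchurn_validation_error")
})

test_that("model frames have the specified rows, columns and nesting", {
  sim <- generate_dataset(tiny_config(n_persons = 20, seed = 2))
  f1 <- build_model_frame(sim$panel, "er_visits", "static1")
  f2 <- build_model_frame(sim$panel, "er_visits", "static2")
  f3 <- build_model_frame(sim$panel, "er_visits", "dynamic3")

  expect_equal(nrow(f1), 20 * 6)
  expect_equal(nrow(f2), 20 * 6)
  expect_equal(nrow(f3), 20 * 5)
  expect_false(any(f3$round == 1))

  c1 <- colnames(frame_matrix(f1))
  c2 <- colnames(frame_matrix(f2))
  c3 <- colnames(frame_matrix(f3))
  expect_equal(setdiff(c2, c1), c("mean_employed", "mean_healthy"))
  expect_true(all(c1 %in% c2))
  expect_true(all(setdiff(c2, "round_2") %in% c3))
  expect_true(all(c("lag_er_visits", "init_er_visits") %in% c3))
  expect_false(any(duplicated(c3)))

  # round dummies: reference is the first modeled round
  expect_true("round_2" %in% c1)
  expect_false("round_1" %in% c1)
  expect_false("round_2" %in% c3)  # dynamic reference round is 2
  expect_true("round_3" %in% c3)
})

test_that("dynamic frame lag and initial columns reproduce a known sequence", {
  p <- make_panel(list(c(1, 1, 1, 1, 1), c(1, 0, 1, 0, 1)),
                  er_visits = list(c(2L, 0L, 1L, 3L, 0L),
                                   c(0L, 0L, 0L, 0L, 0L)))
  f3 <- build_model_frame(p, "er_visits", "dynamic3")
  rows <- f3[f3$person_id == "p001", ]
  expect_equal(rows$lag_er_visits, c(2, 0, 1, 3))
  expect_equal(rows$init_er_visits, rep(2, 4))

  f3log <- build_model_frame(p, "er_visits", "dynamic3", h_form = "log1p")
  rows_log <- f3log[f3log$person_id == "p001", ]
  expect_equal(rows_log$lag_er_visits, log1p(c(2, 0, 1, 3)))

  p2 <- make_panel(list(1))
  expect_error(build_model_frame(p2, "er_visits", "dynamic3"),
               class = "medchurn_validation_error")
})
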
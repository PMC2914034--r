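# Build a small valid panel by hand, specifying only what a test cares
# about; everything else gets innocuous constants.
make_panel <- function(medicaid, er_visits = NULL, outpatient_visits = NULL,
                       income = NULL) {
  stopifnot(is.list(medicaid))
  n <- length(medicaid)
  T_n <- length(medicaid[[1]])
  rows <- lapply(seq_len(n), function(i) {
    tibble::tibble(
      person_id = sprintf("p%03d", i),
      round = seq_len(T_n),
      medicaid = medicaid[[i]],
      employed = rep(c(1L, 0L), length.out = T_n),
      healthy = rep(c(0L, 1L), length.out = T_n),
      income = if (is.null(income)) 100 + 10 * i + seq_len(T_n) else income[[i]],
      er_visits = if (is.null(er_visits)) rep(0L, T_n) else er_visits[[i]],
      outpatient_visits = if (is.null(outpatient_visits)) rep(1L, T_n)
                          else outpatient_visits[[i]],
      inpatient_discharges = rep(0L, T_n),
      rx_fills = rep(2L, T_n),
      age = 30 + i,
      male = i %% 2L,
      married = 0L,
      high_school = 1L,
      white = 1L,
      family_size = 2L,
      chronic_count = 0L
    )
  })
  medchurn::validate_panel(dplyr::bind_rows(rows))
}

# small-but-informative generator settings for fast unit tests
tiny_config <- function(n_persons = 60, seed = 1, ...) {
  medchurn::sim_config(n_persons = n_persons, seed = seed, ...)
}

# brute-force numeric-integration oracles for the marginal likelihoods,
# independent of the closed-form / quadrature implementation paths
oracle_loglik_gamma <- function(y, rates, theta) {
  f <- function(a) {
    vapply(a, function(ai) {
      exp(sum(dpois(y, ai * rates, log = TRUE)) +
            dgamma(ai, shape = theta, rate = theta, log = TRUE))
    }, numeric(1))
  }
  log(integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 0)$value)
}

oracle_loglik_normal <- function(y, eta, sigma) {
  g <- function(u) {
    vapply(u, function(ui) {
      sum(dpois(y, exp(eta + sigma * ui), log = TRUE))
    }, numeric(1))
  }
  g0 <- optimize(g, c(-10, 10), maximum = TRUE)$objective
  f <- function(u) exp(g(u) - g0) * dnorm(u)
  log(integrate(f, -12, 12, rel.tol = 1e-13, abs.tol = 0)$value) + g0
}

# adjacent-difference transition counter written independently of the
# package implementation
oracle_count_transitions <- function(b) {
  n <- 0L
  for (t in seq_len(length(b) - 1)) if (b[t] != b[t + 1]) n <- n + 1L
  n
}
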
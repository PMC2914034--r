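#' Fit a random-effects Poisson model by maximum likelihood
#'
#' Maximizes the sum over persons of the marginal log-likelihood of the
#' chosen mixing family in the coefficient vector and the mixing
#' parameter, using a quasi-Newton optimizer on `(beta, log theta)` (or
#' `(beta, log sigma)`) with analytic gradients.  Starting values are the
#' pooled Poisson fit for `beta` and a method-of-moments dispersion
#' estimate for the mixing parameter, so the fit is deterministic: the
#' same frame and options always give the same result.
#'
#' Standard errors come from the inverse of the observed information
#' (numerical Hessian of the negative log-likelihood at the optimum);
#' incidence rate ratios are `exp(beta)` with delta-method standard
#' errors.
#'
#' @param frame A `mc_frame` from [build_model_frame()].
#' @param mixing `"gamma"` (multiplicative unit-mean gamma effect, closed
#'   form; the default), `"normal"` (additive normal effect on the log
#'   scale, Gauss-Hermite quadrature), or `"pooled"` (no individual
#'   effect).
#' @param quad_nodes Gauss-Hermite nodes for `mixing = "normal"`.
#' @param se Compute standard errors (skip for speed inside simulation
#'   loops).
#' @param start Optional named starting vector for the coefficients.
#' @param control Optional list overriding `nlminb` control parameters.
#' @return An object of class `mc_fit`; see [tidy.mc_fit()] and
#'   [glance.mc_fit()].
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(n_persons = 150, seed = 3))
#' fr <- build_model_frame(sim$panel, "er_visits", "static1")
#' fit <- fit_re_poisson(fr)
#' glance(fit)
fit_re_poisson <- function(frame, mixing = c("gamma", "normal", "pooled"),
                           quad_nodes = 20, se = TRUE, start = NULL,
                           control = list()) {
  mixing <- match.arg(mixing)
  X <- frame_matrix(frame)
  y <- frame$.y
  pid <- match(frame$person_id, unique(frame$person_id))
  n_p <- max(pid)
  ends <- c(which(diff(pid) != 0), length(pid))
  p <- ncol(X)

  qr_x <- qr(X)
  if (qr_x$rank < p) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    abort(paste0("Regressor matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "medchurn_rank_error")
  }

  pooled <- glm.fit(X, y, family = poisson())
  beta0 <- unname(pooled$coefficients)
  if (!is.null(start)) {
    beta0[match(names(start), colnames(X))] <- unname(start)
  }

  # method-of-moments start for the dispersion of the individual effect
  lam0 <- exp(pmin(drop(X %*% beta0), 50))
  s_y <- rowsum_vec(y, ends)
  s_l <- rowsum_vec(lam0, ends)
  ratio <- (s_y + 0.5) / (s_l + 0.5)
  v0 <- min(max(var(ratio), 0.05), 10)

  ctrl <- modifyList(list(rel.tol = 1e-10, iter.max = 500, eval.max = 1000),
                     control)

  if (mixing == "pooled") {
    opt <- nlminb(beta0, nll_pooled, gradient = grad_nll_pooled,
                  y = y, X = X, control = ctrl)
    par <- opt$par
    fn <- function(q) nll_pooled(q, y, X)
    gr <- function(q) grad_nll_pooled(q, y, X)
    mix_est <- NULL
  } else if (mixing == "gamma") {
    par0 <- c(beta0, log(1 / v0))
    opt <- nlminb(par0, nll_gamma, gradient = grad_nll_gamma,
                  y = y, X = X, pid = pid, ends = ends, n_p = n_p,
                  control = ctrl)
    par <- opt$par
    fn <- function(q) nll_gamma(q, y, X, pid, ends, n_p)
    gr <- function(q) grad_nll_gamma(q, y, X, pid, ends, n_p)
    mix_est <- exp(par[p + 1])
  } else {
    gh <- gh_rule(quad_nodes)
    par0 <- c(beta0, 0.5 * log(log(1 + v0)))
    opt <- nlminb(par0, nll_normal, gradient = grad_nll_normal,
                  y = y, X = X, pid = pid, ends = ends, n_p = n_p,
                  gh = gh, control = ctrl)
    par <- opt$par
    fn <- function(q) nll_normal(q, y, X, pid, ends, n_p, gh)
    gr <- function(q) grad_nll_normal(q, y, X, pid, ends, n_p, gh)
    mix_est <- exp(par[p + 1])
  }

  loglik <- -opt$objective
  grad_norm <- max(abs(gr(par)))
  # nlminb's code can report "false convergence" at a genuine optimum
  # under very tight tolerances; the first-order condition is the test
  converged <- is.finite(loglik) && grad_norm < 1e-3 * (1 + abs(loglik))
  if (!converged) {
    warn(paste0("Fit did not converge cleanly (nlminb code ",
                opt$convergence, ", max |gradient| ",
                format(grad_norm, digits = 3), ")."))
  }

  coef <- setNames(par[seq_len(p)], colnames(X))
  se_vec <- rep(NA_real_, length(par))
  vcov <- NULL
  if (se) {
    hess <- try(optimHess(par, fn, gr), silent = TRUE)
    if (!inherits(hess, "try-error")) {
      vcov <- try(solve(hess), silent = TRUE)
      if (!inherits(vcov, "try-error") && all(diag(vcov) > 0)) {
        se_vec <- sqrt(diag(vcov))
      } else {
        vcov <- NULL
        warn("Observed information is not positive definite; standard errors unavailable.")
      }
    }
  }

  mixing_se <- if (mixing == "pooled" || !se || is.na(se_vec[p + 1])) {
    NA_real_
  } else {
    mix_est * se_vec[p + 1]  # delta method through the log link
  }

  structure(
    list(
      spec = attr(frame, "spec"),
      outcome = attr(frame, "outcome"),
      h_form = attr(frame, "h_form"),
      mixing = mixing,
      coefficients = coef,
      std_errors = setNames(se_vec[seq_len(p)], colnames(X)),
      irr = exp(coef),
      irr_se = exp(coef) * se_vec[seq_len(p)],
      mixing_estimate = if (mixing == "pooled") NA_real_ else mix_est,
      mixing_se = mixing_se,
      loglik = loglik,
      iterations = opt$iterations,
      converged = converged,
      grad_norm = grad_norm,
      n_persons = n_p,
      n_obs = length(y),
      quad_nodes = if (mixing == "normal") quad_nodes else NA_integer_,
      vcov = vcov
    ),
    class = "mc_fit"
  )
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.01 ~ "***",
    p < 0.05 ~ "**",
    p < 0.10 ~ "*",
    TRUE ~ ""
  )
}

#' Tidy a random-effects Poisson fit
#'
#' @param x A `mc_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate` (log
#'   scale), `std.error`, `statistic`, `p.value`, `irr`, `irr.se`, and a
#'   `stars` column using the `* p<0.10, ** p<0.05, *** p<0.01`
#'   convention.
#' @method tidy mc_fit
#' @export
tidy.mc_fit <- function(x, ...) {
  z <- x$coefficients / x$std_errors
  p <- 2 * pnorm(-abs(z))
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors),
    statistic = unname(z),
    p.value = unname(p),
    irr = unname(x$irr),
    irr.se = unname(x$irr_se),
    stars = significance_stars(unname(p))
  )
}

#' One-row summary of a random-effects Poisson fit
#'
#' @param x A `mc_fit`.
#' @param ... Unused.
#' @return A tibble with the specification, outcome, mixing family and
#'   estimate, log-likelihood, sample sizes and convergence status.
#' @method glance mc_fit
#' @export
glance.mc_fit <- function(x, ...) {
  tibble(
    spec = x$spec,
    outcome = x$outcome,
    mixing = x$mixing,
    mixing_estimate = x$mixing_estimate,
    mixing_se = x$mixing_se,
    logLik = x$loglik,
    n_obs = x$n_obs,
    n_persons = x$n_persons,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @export
print.mc_fit <- function(x, ...) {
  cat("Random-effects Poisson fit (", x$mixing, " mixing)\n", sep = "")
  cat("  outcome: ", x$outcome, "   specification: ", x$spec, "\n", sep = "")
  cat("  persons: ", x$n_persons, "   observations: ", x$n_obs,
      "   logLik: ", format(x$loglik, digits = 8), "\n", sep = "")
  if (!is.na(x$mixing_estimate)) {
    cat("  mixing parameter: ", format(x$mixing_estimate, digits = 4),
        " (se ", format(x$mixing_se, digits = 3), ")\n", sep = "")
  }
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  print(as.data.frame(tidy(x)), digits = 4)
  invisible(x)
}

#' Forest plot of incidence rate ratios
#'
#' @param object A `mc_fit`.
#' @param drop_terms Terms to omit; by default the intercept and the round
#'   fixed effects, leaving the substantive covariates.
#' @param ... Unused.
#' @return A ggplot: IRR point estimates with 95% confidence intervals on
#'   a log scale, reference line at 1.
#' @method autoplot mc_fit
#' @export
autoplot.mc_fit <- function(object, drop_terms = NULL, ...) {
  td <- tidy(object)
  if (is.null(drop_terms)) {
    drop_terms <- c("intercept", grep("^round_", td$term, value = TRUE))
  }
  td <- td[!td$term %in% drop_terms, , drop = FALSE]
  td$lo <- exp(td$estimate - qnorm(0.975) * td$std.error)
  td$hi <- exp(td$estimate + qnorm(0.975) * td$std.error)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$irr,
                                   y = stats::reorder(.data$term, .data$irr))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Incidence rate ratio (95% CI)", y = NULL,
      title = paste0(object$outcome, " - ", object$spec),
      subtitle = paste0(object$mixing, "-mixed random-effects Poisson")
    )
}

#' Fit the three specifications of one outcome
#'
#' Convenience wrapper running the baseline random-effects specification,
#' the correlated-random-effects (within-means) specification, and the
#' dynamic specification with lagged and initial outcomes, so a
#' three-column regression table can be assembled.
#'
#' @inheritParams build_model_frame
#' @inheritParams fit_re_poisson
#' @return A named list of three `mc_fit` objects
#'   (`static1`, `static2`, `dynamic3`) of class `mc_spec_set`.
#' @export
compare_specs <- function(panel, outcome, mixing = "gamma",
                          h_form = "identity", se = TRUE, ...) {
  specs <- c("static1", "static2", "dynamic3")
  fits <- purrr::map(specs, function(s) {
    fit_re_poisson(build_model_frame(panel, outcome, s, h_form),
                   mixing = mixing, se = se, ...)
  })
  structure(setNames(fits, specs), class = "mc_spec_set")
}

#' @method tidy mc_spec_set
#' @export
tidy.mc_spec_set <- function(x, ...) {
  purrr::list_rbind(purrr::imap(unclass(x), function(f, s) {
    dplyr::mutate(tidy(f), spec = s, .before = 1)
  }))
}

#' @method glance mc_spec_set
#' @export
glance.mc_spec_set <- function(x, ...) {
  purrr::list_rbind(purrr::map(unclass(x), glance))
}

#' @method autoplot mc_spec_set
#' @export
autoplot.mc_spec_set <- function(object, drop_terms = NULL, ...) {
  td <- tidy(object)
  if (is.null(drop_terms)) {
    drop_terms <- c("intercept", grep("^round_", td$term, value = TRUE))
  }
  td <- td[!td$term %in% drop_terms, , drop = FALSE]
  td$lo <- exp(td$estimate - qnorm(0.975) * td$std.error)
  td$hi <- exp(td$estimate + qnorm(0.975) * td$std.error)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$irr, y = .data$term,
                                   colour = .data$spec)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Incidence rate ratio (95% CI)", y = NULL,
                  colour = "Specification")
}
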
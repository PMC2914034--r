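#' Poisson log probability mass
#'
#' Direct evaluation of `y * log(rate) - rate - log(y!)` using `lgamma`
#' for the factorial, stable for counts up to at least 1e4.
#'
#' @param y Non-negative integer count(s).
#' @param rate Positive Poisson mean(s).
#' @return Log probability mass, vectorized over `y` and `rate`.
#' @export
poisson_logpmf <- function(y, rate) {
  if (any(rate <= 0)) {
    abort("`rate` must be positive.", class = "medchurn_domain_error")
  }
  if (any(y < 0 | y != round(y))) {
    abort("`y` must be a non-negative integer.",
          class = "medchurn_domain_error")
  }
  y * log(rate) - rate - lgamma(y + 1)
}

#' Marginal log-likelihood of one person's counts under gamma mixing
#'
#' The individual effect is a multiplicative gamma variable with mean 1
#' and variance `1/theta`, shared across the person's rounds.  Integrating
#' it out of the product of Poisson kernels analytically gives the closed
#' form
#' \deqn{\sum_t [y_t \log\lambda_t - \log y_t!] +
#'       \log\Gamma(\theta + S_y) - \log\Gamma(\theta) +
#'       \theta\log\theta - (\theta + S_y)\log(\theta + S_\lambda)}
#' with \eqn{S_y = \sum_t y_t} and \eqn{S_\lambda = \sum_t \lambda_t}.
#' This is the likelihood behind the random-effects Poisson panel
#' estimator.
#'
#' @param y Vector of counts over the person's rounds.
#' @param rates Vector of positive conditional means, same length.
#' @param theta Positive gamma shape (precision); the effect's variance is
#'   `1/theta`, so `theta -> Inf` recovers the pooled Poisson model.
#' @return The marginal log-likelihood (a scalar).
#' @export
loglik_person_gamma <- function(y, rates, theta) {
  if (length(y) != length(rates)) {
    abort("`y` and `rates` must have equal length.",
          class = "medchurn_domain_error")
  }
  if (!all(is.finite(rates)) || any(rates <= 0)) {
    abort("`rates` must be finite and positive.",
          class = "medchurn_domain_error")
  }
  if (!is.finite(theta) || theta <= 0) {
    abort("`theta` must be positive.", class = "medchurn_domain_error")
  }
  s_y <- sum(y)
  s_l <- sum(rates)
  sum(y * log(rates) - lgamma(y + 1)) +
    lgamma(theta + s_y) - lgamma(theta) +
    theta * log(theta) - (theta + s_y) * log(theta + s_l)
}

# Gauss-Hermite rule adapted to the standard-normal weight:
# integral f(u) phi(u) du = sum w_k f(v_k)
gh_rule <- function(nodes) {
  if (nodes < 1) {
    abort("`nodes` must be >= 1.", class = "medchurn_domain_error")
  }
  gh <- pracma::gaussHermite(nodes)
  list(v = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

#' Marginal log-likelihood of one person's counts under log-normal mixing
#'
#' The individual effect is additive normal on the log scale: counts are
#' Poisson with mean `exp(eta_t + sigma * u)`, `u ~ N(0, 1)` shared across
#' rounds.  The integral over `u` has no closed form and is approximated
#' by adaptive Gauss-Hermite quadrature: the rule is recentred at the
#' mode of the integrand and rescaled by its curvature, so accuracy is
#' essentially independent of `sigma` and a modest number of nodes
#' suffices.  With `sigma = 0` the pooled Poisson log-likelihood is
#' returned exactly.
#'
#' @param y Vector of counts over the person's rounds.
#' @param eta Vector of linear predictors (log conditional means at
#'   `u = 0`), same length as `y`.
#' @param sigma Non-negative standard deviation of the individual effect.
#' @param nodes Number of quadrature nodes (default 20).
#' @return The approximate marginal log-likelihood (a scalar).
#' @export
loglik_person_normal <- function(y, eta, sigma, nodes = 20) {
  if (length(y) != length(eta)) {
    abort("`y` and `eta` must have equal length.",
          class = "medchurn_domain_error")
  }
  if (sigma < 0) {
    abort("`sigma` must be non-negative.", class = "medchurn_domain_error")
  }
  if (sigma == 0) {
    return(sum(poisson_logpmf(y, exp(eta))))
  }
  gh <- gh_rule(nodes)
  a <- sum(y * eta - lgamma(y + 1))
  agq_normal(a, sum(y), sum(exp(eta)), sigma, gh)$ll
}

# Adaptive Gauss-Hermite for the log-normal-mixed Poisson integral,
# vectorized over persons.  The person-level integrand depends on the
# data only through a_i = sum(y eta - log y!), S_y and S_lambda:
#   G_i(u) = a_i + sigma u S_y,i - e^{sigma u} S_lambda,i - u^2/2 - log(2pi)/2
# G is strictly concave, so the Newton mode search always converges.
agq_normal <- function(a, s_y, s_l, sigma, gh) {
  u <- rep(0, length(a))
  for (it in 1:50) {
    es <- exp(sigma * u)
    g1 <- sigma * (s_y - es * s_l) - u
    g2 <- -sigma^2 * es * s_l - 1
    step <- g1 / g2
    u <- u - step
    if (max(abs(step)) < 1e-12) break
  }
  tau <- 1 / sqrt(sigma^2 * exp(sigma * u) * s_l + 1)
  # nodes u_ik = u_i + sqrt(2) tau_i x_k; weight e^{-x^2} removed
  x <- gh$v / sqrt(2)                     # raw Hermite abscissae
  uk <- outer(u, rep(1, length(x))) + sqrt(2) * tau %o% x
  Gk <- a + sigma * uk * s_y - exp(sigma * uk) * s_l -
    uk^2 / 2 - log(2 * pi) / 2
  lw <- sweep(Gk + outer(rep(1, length(a)), x^2), 2,
              log(gh$w) + 0.5 * log(pi), "+")
  m <- apply(lw, 1, max)
  ll <- m + log(rowSums(exp(lw - m))) + log(sqrt(2) * tau)
  pk <- exp(lw - m)
  pk <- pk / rowSums(pk)
  list(ll = ll, nodes = uk, weights = pk)
}

# ---- vectorized dataset-level negative log-likelihoods and gradients ----
# pid: integer person index 1..n_p, rows grouped by person.

big_penalty <- 1e10

nll_pooled <- function(beta, y, X) {
  eta <- drop(X %*% beta)
  if (any(eta > 50)) return(big_penalty)
  -sum(y * eta - exp(eta) - lgamma(y + 1))
}

grad_nll_pooled <- function(beta, y, X) {
  eta <- drop(X %*% beta)
  if (any(eta > 50)) return(rep(0, length(beta)))
  -drop(crossprod(X, y - exp(eta)))
}

nll_gamma <- function(par, y, X, pid, ends, n_p) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- exp(par[p + 1])
  eta <- drop(X %*% beta)
  if (any(eta > 50) || !is.finite(theta) || theta <= 0) return(big_penalty)
  lam <- exp(eta)
  s_y <- rowsum_vec(y, ends)
  s_l <- rowsum_vec(lam, ends)
  ll <- sum(y * eta - lgamma(y + 1)) +
    sum(lgamma(theta + s_y)) - n_p * lgamma(theta) +
    n_p * theta * log(theta) - sum((theta + s_y) * log(theta + s_l))
  if (!is.finite(ll)) return(big_penalty)
  -ll
}

grad_nll_gamma <- function(par, y, X, pid, ends, n_p) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- exp(par[p + 1])
  eta <- drop(X %*% beta)
  if (any(eta > 50)) return(rep(0, p + 1))
  lam <- exp(eta)
  s_y <- rowsum_vec(y, ends)
  s_l <- rowsum_vec(lam, ends)
  w <- (theta + s_y) / (theta + s_l)
  g_beta <- drop(crossprod(X, y - lam * w[pid]))
  g_theta <- sum(digamma(theta + s_y) - digamma(theta) + log(theta) + 1 -
                   log(theta + s_l) - w)
  -c(g_beta, g_theta * theta)  # chain rule through log(theta)
}

nll_normal <- function(par, y, X, pid, ends, n_p, gh) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  sigma <- exp(par[p + 1])
  eta <- drop(X %*% beta)
  if (any(eta > 50) || !is.finite(sigma)) return(big_penalty)
  a <- rowsum_vec(y * eta - lgamma(y + 1), ends)
  s_y <- rowsum_vec(y, ends)
  s_l <- rowsum_vec(exp(eta), ends)
  ll <- sum(agq_normal(a, s_y, s_l, sigma, gh)$ll)
  if (!is.finite(ll)) return(big_penalty)
  -ll
}

# score evaluated under the quadrature posterior over the individual
# effect: E[.|y_i] uses the adapted node weights
grad_nll_normal <- function(par, y, X, pid, ends, n_p, gh) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  sigma <- exp(par[p + 1])
  eta <- drop(X %*% beta)
  if (any(eta > 50)) return(rep(0, p + 1))
  lam <- exp(eta)
  a <- rowsum_vec(y * eta - lgamma(y + 1), ends)
  s_y <- rowsum_vec(y, ends)
  s_l <- rowsum_vec(lam, ends)
  q <- agq_normal(a, s_y, s_l, sigma, gh)
  ev <- exp(sigma * q$nodes)
  e_exp <- rowSums(q$weights * ev)             # E[exp(sigma u) | y_i]
  e_u <- rowSums(q$weights * q$nodes)          # E[u | y_i]
  e_uexp <- rowSums(q$weights * q$nodes * ev)  # E[u exp(sigma u) | y_i]
  g_beta <- drop(crossprod(X, y - lam * e_exp[pid]))
  g_sigma <- sum(s_y * e_u - s_l * e_uexp)
  -c(g_beta, g_sigma * sigma)
}

# group sums for rows sorted and contiguous by person: `ends` holds the
# index of each person's last row
rowsum_vec <- function(x, ends) {
  cs <- cumsum(x)
  diff(c(0, cs[ends]))
}
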
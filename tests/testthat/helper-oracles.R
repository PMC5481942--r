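# Independent numerical oracles used to check the closed-form model
# arithmetic. These deliberately avoid the package's own code paths.

# Brute-force Bayes on a grid: prior density times likelihood density,
# normalized; returns the posterior mean and variance by numerical moments.
grid_bayes_oracle <- function(prior_mean, prior_var, lik_mean, lik_prec,
                              lim = 12, step = 1e-3) {
  x <- seq(-lim, lim, by = step)
  d <- dnorm(x, prior_mean, sqrt(prior_var))
  if (lik_prec > 0) d <- d * dnorm(x, lik_mean, sqrt(1 / lik_prec))
  d <- d / sum(d)
  m <- sum(x * d)
  c(mean = m, var = sum((x - m)^2 * d))
}

# KL divergence by adaptive quadrature of the defining integral.
kl_numeric_oracle <- function(p_mean, p_var, q_mean, q_var) {
  f <- function(x) {
    p <- dnorm(x, p_mean, sqrt(p_var))
    ifelse(p > 0,
           p * (dnorm(x, p_mean, sqrt(p_var), log = TRUE) -
                  dnorm(x, q_mean, sqrt(q_var), log = TRUE)),
           0)
  }
  integrate(f, p_mean - 20 * sqrt(p_var), p_mean + 20 * sqrt(p_var),
            rel.tol = 1e-12, abs.tol = 1e-12, subdivisions = 2000L)$value
}

# 1-D numerical maximizer of the single-trial objective in the prior mean.
# The objective is quadratic in mu, so the central-difference gradient is
# exact (up to round-off) and its root is the optimum.
profile_mean_oracle <- function(s2, w, m_std, r1, r2) {
  P <- 1 / s2 + w
  a <- (1 / s2) / P
  obj <- function(mu) {
    dnorm(r1, mu, sqrt(s2), log = TRUE) +
      dnorm(r2, a * mu + (1 - a) * m_std, sqrt(1 / P), log = TRUE)
  }
  h <- 1e-4
  grad <- function(mu) (obj(mu + h) - obj(mu - h)) / (2 * h)
  uniroot(grad, c(-100, 100), tol = 1e-13)$root
}

# Profiled participant log-likelihood evaluated at given structural
# parameters (used for the optimizer-vs-grid check).
profiled_loglik_at <- function(trials, s2_low, s2_high, w_low, w_high) {
  s2 <- ifelse(trials$high_conf == 1, s2_high, s2_low)
  w <- ifelse(trials$many_reviews == 1, w_high, w_low)
  mu <- profile_prior_mean(s2, w, trials$m_std, trials$r1, trials$r2)
  names(mu) <- as.character(trials$product_id)
  p <- participant_params(mu, s2_low, s2_high, w_low, w_high)
  sum(trial_loglik(p, trials))
}
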
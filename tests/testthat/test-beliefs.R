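# The conjugate-update core: posterior arithmetic, KL divergence, resistance.

test_that("posterior update matches the conjugate closed form in easy cases", {
  post <- posterior_update(gaussian_belief(0, 1), 1, 1)
  expect_equal(post$mean, 0.5)
  expect_equal(post$variance, 0.5)

  # zero evidence precision leaves the prior untouched
  prior <- gaussian_belief(c(-0.4, 0.2), c(0.8, 2.5))
  post <- posterior_update(prior, 3, 0)
  expect_equal(post$mean, prior$mean)
  expect_equal(post$variance, prior$variance)
})

test_that("posterior update agrees with brute-force grid Bayes", {
  set.seed(101)
  for (i in 1:200) {
    pm <- runif(1, -2, 2); pv <- runif(1, 0.1, 5)
    lm <- runif(1, -2, 2); lp <- runif(1, 0, 5)
    post <- posterior_update(gaussian_belief(pm, pv), lm, lp)
    oracle <- grid_bayes_oracle(pm, pv, lm, lp)
    expect_equal(post$mean, oracle[["mean"]], tolerance = 1e-4)
    expect_equal(post$variance, oracle[["var"]], tolerance = 1e-4)
  }
  # the spec-level spot case
  post <- posterior_update(gaussian_belief(0.2, 0.5), 1.0, 4)
  oracle <- grid_bayes_oracle(0.2, 0.5, 1.0, 4)
  expect_equal(post$mean, oracle[["mean"]], tolerance = 1e-4)
  expect_equal(post$variance, oracle[["var"]], tolerance = 1e-4)
  expect_equal(post$mean, 11 / 15, tolerance = 1e-10)
  expect_equal(post$variance, 1 / 6, tolerance = 1e-10)
})

test_that("KL closed form agrees with numerical integration and is a
          divergence", {
  expect_equal(kl_divergence(gaussian_belief(0.3, 1.2),
                             gaussian_belief(0.3, 1.2)), 0)
  expect_equal(kl_divergence(gaussian_belief(0, 1), gaussian_belief(1, 1)),
               0.5)
  expect_equal(kl_divergence(gaussian_belief(0, 1), gaussian_belief(0, 0.5)),
               kl_numeric_oracle(0, 1, 0, 0.5), tolerance = 1e-6)

  set.seed(202)
  for (i in 1:200) {
    pm <- runif(1, -3, 3); pv <- runif(1, 0.05, 20)
    qm <- runif(1, -3, 3); qv <- runif(1, 0.05, 20)
    kl <- kl_divergence(gaussian_belief(pm, pv), gaussian_belief(qm, qv))
    expect_gte(kl, 0)
    expect_equal(kl, kl_numeric_oracle(pm, pv, qm, qv), tolerance = 1e-6)
  }
})

test_that("KL grows with evidence precision; resistance shrinks", {
  prior <- gaussian_belief(0, 1)
  precs <- c(0.1, 0.5, 1, 2, 5, 20)
  kls <- vapply(precs, function(w)
    kl_divergence(prior, posterior_update(prior, 1.5, w)), numeric(1))
  expect_true(all(diff(kls) > 0))
  res <- resistance_weight(1, precs)
  expect_true(all(diff(res) < 0))
})

test_that("resistance has the two defining endpoints and is symmetric", {
  expect_identical(resistance_weight(1, 0), 1)
  expect_identical(resistance_weight(2.7, 0), 1)
  # prior precision -> 0 limit
  expect_true(all(diff(resistance_weight(10^-(1:6), 1)) < 0))
  expect_lt(resistance_weight(1e-9, 1), 1e-8)
  expect_equal(resistance_weight(3, 3), 0.5)
  expect_error(resistance_weight(0, 1), "positive")
  expect_error(resistance_weight(1, -0.1), "non-negative")
})

test_that("posterior mean is a convex combination with weight equal to the
          resistance", {
  set.seed(303)
  for (i in 1:50) {
    pm <- runif(1, -2, 2); pv <- runif(1, 0.1, 5)
    lm <- runif(1, -2, 2); lp <- runif(1, 0, 5)
    prior <- gaussian_belief(pm, pv)
    post <- posterior_update(prior, lm, lp)
    res <- resistance_weight(1 / pv, lp)
    expect_equal(post$mean, res * pm + (1 - res) * lm, tolerance = 1e-12)
    # and the posterior mean lies weakly between prior mean and evidence mean
    expect_gte(post$mean, min(pm, lm) - 1e-12)
    expect_lte(post$mean, max(pm, lm) + 1e-12)
    # precision additivity
    expect_equal(1 / post$variance, 1 / pv + lp, tolerance = 1e-10)
  }
})

test_that("trial log-likelihood is the sum of prior and posterior log
          densities", {
  p <- participant_params(c(a = 0), s2_low = 1, s2_high = 1,
                          w_low = 0, w_high = 0)
  tr <- data.frame(participant_id = "x", product_id = "a", r1 = 0, r2 = 0,
                   m_std = 2, high_conf = 0L, many_reviews = 0L)
  expect_equal(trial_loglik(p, tr), -log(2 * pi))

  # moving r1 off the prior mean can only lower it
  lls <- vapply(c(0, 0.5, 1, 2), function(shift) {
    tr$r1 <- shift
    trial_loglik(p, tr)
  }, numeric(1))
  expect_true(all(diff(lls) < 0))

  # randomized agreement with direct density recomputation
  set.seed(404)
  for (i in 1:50) {
    mu <- rnorm(1); s2l <- runif(1, 0.2, 3); s2h <- runif(1, 0.05, 1) * s2l
    wl <- runif(1, 0, 2); wh <- wl + runif(1, 0, 2)
    hc <- rbinom(1, 1, 0.5); mr <- rbinom(1, 1, 0.5)
    tr <- data.frame(participant_id = "x", product_id = "a",
                     r1 = rnorm(1), r2 = rnorm(1), m_std = rnorm(1),
                     high_conf = hc, many_reviews = mr)
    p <- participant_params(c(a = mu), s2l, s2h, wl, wh)
    s2 <- if (hc == 1) s2h else s2l
    w <- if (mr == 1) wh else wl
    postv <- 1 / (1 / s2 + w)
    postm <- (mu / s2 + w * tr$m_std) * postv
    direct <- dnorm(tr$r1, mu, sqrt(s2), log = TRUE) +
      dnorm(tr$r2, postm, sqrt(postv), log = TRUE)
    expect_equal(trial_loglik(p, tr), direct, tolerance = 1e-10)
  }
})

test_that("zero review weight means zero update and full resistance", {
  n <- 30
  mu <- rnorm(n)
  names(mu) <- sprintf("z%02d", 1:n)
  p <- participant_params(mu, s2_low = 1.1, s2_high = 0.6,
                          w_low = 0, w_high = 0)
  tr <- data.frame(participant_id = "x", product_id = names(mu),
                   r1 = rnorm(n), r2 = rnorm(n), m_std = rnorm(n),
                   high_conf = rbinom(n, 1, 0.5),
                   many_reviews = rbinom(n, 1, 0.5))
  d <- derive_trials(p, tr)
  expect_identical(d$kl, rep(0, n))
  expect_identical(d$resistance, rep(1, n))
  expect_equal(participant_resistance(d), 1)
  expect_equal(d$post_mean, d$prior_mean)
})

test_that("belief and parameter constructors reject invalid shapes", {
  expect_error(gaussian_belief(0, 0), "positive")
  expect_error(gaussian_belief(0, -1), "positive")
  expect_error(participant_params(c(a = 0), s2_low = 0.5, s2_high = 0.8,
                                  w_low = 0, w_high = 1), "s2_high")
  expect_error(participant_params(c(a = 0), s2_low = 1, s2_high = 0.5,
                                  w_low = 1, w_high = 0.2), "w_low")
  expect_error(prior_for_trial(
    participant_params(c(a = 0), 1, 1, 0, 0),
    data.frame(product_id = "b", high_conf = 0L)), "no prior mean")
})
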
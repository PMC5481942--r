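# Profile-likelihood fitting: closed-form profiled means, parameter
# recovery, degenerate cases, optimizer behaviour.

test_that("profiled prior mean has its closed-form special cases", {
  # no review weight: plain average of the two ratings
  expect_equal(profile_prior_mean(1.3, 0, m_std = 5, r1 = 0.2, r2 = 0.8),
               0.5)
  # perfect agreement is a fixed point
  expect_equal(profile_prior_mean(0.7, 2.1, m_std = 0.4, r1 = 0.4, r2 = 0.4),
               0.4)
})

test_that("profiled prior mean matches 1-D numerical optimization", {
  set.seed(42)
  for (i in 1:200) {
    s2 <- runif(1, 0.05, 5); w <- runif(1, 0, 8)
    m <- rnorm(1, 0, 2); r1 <- rnorm(1, 0, 2); r2 <- rnorm(1, 0, 2)
    expect_equal(profile_prior_mean(s2, w, m, r1, r2),
                 profile_mean_oracle(s2, w, m, r1, r2), tolerance = 1e-8)
  }
  # the spot case with a strong likelihood
  expect_equal(profile_prior_mean(1, 4, 1, 0, 0.9),
               profile_mean_oracle(1, 4, 1, 0, 0.9), tolerance = 1e-8)
})

test_that("no single profiled mean can be improved at the optimum", {
  tr <- model_scale_participant(n = 80, seed = 21)
  fit <- fit_participant(tr, n_restarts = 4, seed = 22)
  base <- trial_loglik(fit$params, tr)  # per-trial contributions
  for (delta in c(-0.01, 0.01)) {
    pp <- fit$params
    pp$prior_means <- pp$prior_means + delta
    bumped <- trial_loglik(pp, tr)
    # each trial depends on its own mean only, so compare trial-wise
    expect_true(all(bumped <= base + 1e-10))
  }
})

test_that("a zero-weight, low-noise participant shows no detectable review
          influence", {
  # prior noise ~0.04 so the profiled means should track R1 almost exactly;
  # with a tight prior the likelihood is nearly flat in w, so the stable
  # diagnostics are the resistance and the update magnitude, not w itself
  set.seed(33)
  n <- 210
  mu <- rnorm(n)
  hc <- as.integer(rnorm(n) > 0); mr <- as.integer(runif(n) > 0.5)
  s2 <- ifelse(hc == 1, 0.03, 0.05)
  tr <- data.frame(participant_id = "p1",
                   product_id = sprintf("t%03d", 1:n),
                   r1 = mu + sqrt(s2) * rnorm(n),
                   r2 = mu + sqrt(s2) * rnorm(n),
                   m_std = rnorm(n, 1.5, 1),
                   high_conf = hc, many_reviews = mr)
  fit <- fit_participant(tr, n_restarts = 6, seed = 34)
  expect_gte(fit$corr_prior_r1, 0.99)
  d <- derive_trials(fit$params, tr)
  expect_gt(participant_resistance(d), 0.95)
  expect_lt(mean(d$kl), 0.01)
})

test_that("structural parameters are recovered on model-scale cohorts", {
  sim <- simulate_cohort(cohort_spec(n_participants = 8, seed = 61))
  fit <- fit_belief_model(sim$latent, n_restarts = 6, seed = 62)
  truth <- as.matrix(sim$true_params[, c("s2_low", "s2_high",
                                         "w_low", "w_high")])
  rel_err <- abs(coef(fit) - truth) / truth
  expect_lt(median(rel_err), 0.25)
  # and the ordering constraints hold for every participant by construction
  expect_true(all(coef(fit)[, "w_high"] >= coef(fit)[, "w_low"]))
  expect_true(all(coef(fit)[, "s2_high"] <= coef(fit)[, "s2_low"]))
})

test_that("duplicating a participant's trials leaves the estimate alone", {
  tr <- model_scale_participant(n = 120, seed = 51)
  f1 <- fit_participant(tr, n_restarts = 5, seed = 52)
  doubled <- rbind(tr, tr)
  f2 <- fit_participant(doubled, n_restarts = 5, seed = 52)
  for (par in c("s2_low", "s2_high", "w_low", "w_high")) {
    expect_equal(f2$params[[par]], f1$params[[par]], tolerance = 1e-3)
  }
})

test_that("the multi-start procedure is stable at realistic trial counts", {
  # individual restarts may land on local optima; the best-of-10 objective
  # must not depend on the restart draws
  tr <- model_scale_participant(n = 210, seed = 71)
  best <- vapply(1:4, function(k) {
    fit_participant(tr, n_restarts = 10, seed = 72 + k)$profile_loglik
  }, numeric(1))
  expect_lt(diff(range(best)), 1e-4)
  fit <- fit_participant(tr, n_restarts = 10, seed = 72)
  expect_true(fit$converged)
  expect_equal(fit$n_restarts_used, 10L)
  # and most restarts find the same optimum
  expect_gte(sum(abs(fit$restart_logliks - fit$profile_loglik) < 1e-4), 5L)
})

test_that("a coarse grid over the structural parameters never beats the
          optimizer", {
  set.seed(81)
  tr <- model_scale_participant(n = 3, seed = 81)
  fit <- suppressWarnings(
    fit_participant(tr, n_restarts = 8, seed = 82, df_correct = FALSE))
  grid <- exp(seq(log(0.1), log(10), length.out = 7))
  wgrid <- c(0, exp(seq(log(0.05), log(8), length.out = 6)))
  best_grid <- -Inf
  for (s2l in grid) for (s2h in grid[grid <= s2l])
    for (wl in wgrid) for (wh in wgrid[wgrid >= wl]) {
      ll <- profiled_loglik_at(tr, s2l, s2h, wl, wh)
      if (ll > best_grid) best_grid <- ll
    }
  expect_gte(fit$profile_loglik, best_grid - 1e-3)
})

test_that("the degrees-of-freedom correction undoes the profile-ML scale
          shrinkage but not the weights", {
  tr <- model_scale_participant(n = 210, seed = 91)
  raw <- fit_participant(tr, n_restarts = 5, seed = 92, df_correct = FALSE)
  cor_ <- fit_participant(tr, n_restarts = 5, seed = 92, df_correct = TRUE)
  expect_equal(cor_$params$s2_low, 2 * raw$params$s2_low, tolerance = 1e-8)
  expect_equal(cor_$params$w_high, raw$params$w_high / 2, tolerance = 1e-8)
  # the profiled means and fit-quality correlations are invariant
  expect_equal(cor_$params$prior_means, raw$params$prior_means,
               tolerance = 1e-8)
  expect_equal(cor_$corr_prior_r1, raw$corr_prior_r1, tolerance = 1e-10)
  expect_equal(cor_$corr_post_r2, raw$corr_post_r2, tolerance = 1e-10)
})

test_that("derived measures line up with the bayes core trial by trial", {
  tr <- model_scale_participant(n = 60, seed = 95)
  fit <- fit_participant(tr, n_restarts = 4, seed = 96)
  d <- derive_trials(fit$params, tr)
  expect_equal(nrow(d), 60L)
  # spot-check one trial by hand
  i <- 17
  s2 <- if (tr$high_conf[i] == 1) fit$params$s2_high else fit$params$s2_low
  w <- if (tr$many_reviews[i] == 1) fit$params$w_high else fit$params$w_low
  mu <- unname(fit$params$prior_means[as.character(tr$product_id[i])])
  pv <- 1 / (1 / s2 + w)
  pm <- (mu / s2 + w * tr$m_std[i]) * pv
  expect_equal(d$post_mean[i], pm, tolerance = 1e-12)
  expect_equal(d$post_var[i], pv, tolerance = 1e-12)
  expect_equal(d$kl[i],
               0.5 * log(pv / s2) + (s2 + (mu - pm)^2) / (2 * pv) - 0.5,
               tolerance = 1e-12)
  expect_equal(d$resistance[i], (1 / s2) / (1 / s2 + w), tolerance = 1e-12)
  # posterior precision additivity across all trials
  expect_equal(1 / d$post_var,
               1 / d$prior_var + d$likelihood_precision, tolerance = 1e-10)
})

test_that("precision-confidence check behaves at both extremes", {
  tr <- model_scale_participant(n = 210, seed = 97)
  fit <- fit_belief_model(tr, n_restarts = 4, seed = 98)
  prec <- 1 / fit$derived$post_var

  # confidence that is a strictly increasing function of precision
  fit$trials$c2 <- 2 * prec + 1
  expect_equal(unname(precision_confidence(fit)), 1, tolerance = 1e-12)

  # independent noise: near-zero correlation
  set.seed(99)
  fit$trials$c2 <- rnorm(210)
  expect_lt(abs(precision_confidence(fit)), 0.2)

  fit$trials$c2 <- rep(1, 210)
  expect_error(precision_confidence(fit), "zero variance")
})

test_that("cohort fit object supports the standard model generics", {
  sim <- small_cohort(seed = 14, n_participants = 3, n_products = 50)
  prep <- prepare_trials(sim$trials, sim$reviews)
  fit <- fit_belief_model(prep, n_restarts = 3, seed = 15)

  expect_s3_class(fit, "belief_fit")
  expect_equal(dim(coef(fit)), c(3L, 4L))
  expect_equal(length(fitted(fit)), nrow(prep))
  expect_equal(residuals(fit), prep$r2 - fitted(fit))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, newdata = prep), fitted(fit), tolerance = 1e-12)
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), sum(fit$params$loglik))
  expect_equal(attr(ll, "df"), 3L * 4L + nrow(prep))

  simdat <- simulate(fit, nsim = 2, seed = 5)
  expect_equal(nrow(simdat), 2L * nrow(prep))
  expect_identical(simulate(fit, nsim = 2, seed = 5), simdat)

  res <- resistance_by_participant(fit)
  expect_equal(length(res), 3L)
  expect_true(all(res >= 0 & res <= 1))
  expect_equal(unname(res),
               unname(tapply(fit$derived$resistance,
                             fit$derived$participant_id, mean)[names(res)]))

  expect_output(print(fit), "participants")
  expect_output(print(summary(fit)), "resistance")
})
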
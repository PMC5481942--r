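# Small programmatic fixtures shared across test files.

# A hand-sized valid trials table: 2 participants x 3 products, histograms
# consistent with their counts and means.
toy_raw_trials <- function() {
  reviews <- data.frame(
    product_id = c("a", "b", "c"),
    n_reviews = c(4L, 10L, 3L),
    hist_1 = c(0L, 1L, 0L), hist_2 = c(1L, 1L, 0L), hist_3 = c(1L, 2L, 1L),
    hist_4 = c(1L, 3L, 1L), hist_5 = c(1L, 3L, 1L),
    stringsAsFactors = FALSE)
  hist <- as.matrix(reviews[, paste0("hist_", 1:5)])
  reviews$mean_stars <- as.vector(hist %*% (1:5)) / reviews$n_reviews
  trials <- expand.grid(participant_id = c("p1", "p2"),
                        product_id = c("a", "b", "c"),
                        stringsAsFactors = FALSE)
  set.seed(420)
  trials$r1_raw <- round(runif(6, 50, 450), 3)
  trials$c1_raw <- round(runif(6, 50, 450), 3)
  trials$r2_raw <- round(runif(6, 50, 450), 3)
  trials$c2_raw <- round(runif(6, 50, 450), 3)
  list(trials = trials, reviews = reviews)
}

# Simulate one participant's trials directly on the model scale (no slider
# back-mapping), for focused fitter tests.
model_scale_participant <- function(n = 210, s2_low = 0.6, s2_high = 0.35,
                                    w_low = 0.5, w_high = 1.4, seed = 1,
                                    m_mean = 1.5, m_sd = 1) {
  set.seed(seed)
  mu <- rnorm(n)
  hc <- as.integer(rnorm(n) > 0)
  mr <- as.integer(runif(n) > 0.5)
  s2 <- ifelse(hc == 1, s2_high, s2_low)
  w <- ifelse(mr == 1, w_high, w_low)
  m <- rnorm(n, m_mean, m_sd)
  r1 <- mu + sqrt(s2) * rnorm(n)
  P <- 1 / s2 + w
  pm <- (mu / s2 + w * m) / P
  r2 <- pm + rnorm(n) / sqrt(P)
  data.frame(participant_id = "p1", product_id = sprintf("t%03d", seq_len(n)),
             r1 = r1, r2 = r2, m_std = m, high_conf = hc, many_reviews = mr,
             mu_true = mu, stringsAsFactors = FALSE)
}

small_cohort <- function(seed = 7, n_participants = 4, n_products = 60, ...) {
  simulate_cohort(cohort_spec(n_participants = n_participants,
                              n_products = n_products, seed = seed, ...))
}
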
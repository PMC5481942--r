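# Seeded synthetic-cohort generator: review summaries with Amazon-like
# statistics plus two-phase rating data drawn from the belief-updating model
# itself, so every downstream stage can run and be tested without a download.

#' Cohort specification for the synthetic-data generator
#'
#' Collects every distributional choice the generator makes. Defaults emulate
#' the study conditions: 18 participants rating 210 products; review means
#' concentrated near 4 stars (truncated normal on 1-5); heavy-tailed reviewer
#' counts (log-normal, clamped to roughly 3-2000); participant-level
#' structural parameters drawn uniformly from realistic intervals on the
#' standardized rating scale; and a confidence report linked to the log
#' posterior precision with carryover from initial confidence, a penalty for
#' disagreeing with the consensus, a rating-extremity bonus, and Gaussian
#' report noise. Raw sliders are reconstructed through participant-specific
#' jittered affine maps onto `[0, 500]`, so the z-scoring stage is exercised
#' non-trivially.
#'
#' @param n_participants,n_products Cohort dimensions (defaults 18, 210).
#' @param review_count_meanlog,review_count_sdlog,review_count_range
#'   Log-normal law (and clamp range) for reviewer counts.
#' @param star_mean,star_sd,star_range Truncated-normal law for product star
#'   means; `star_within_sd` is the reviewer-to-reviewer spread used to shape
#'   each 5-bin histogram.
#' @param star_within_sd See above.
#' @param s2_low_range Uniform range for the low-confidence prior variance.
#' @param s2_ratio_range Uniform range for `s2_high / s2_low` (in (0, 1]; high
#'   confidence narrows the prior).
#' @param w_low_range Uniform range for the few-review perceived precision.
#' @param w_gap_range Uniform range for `w_high - w_low` (>= 0).
#' @param conf_carryover Loading of initial confidence on second confidence.
#' @param conf_slope Slope of second confidence on log posterior precision.
#' @param conf_conflict Confidence penalty per unit of `|R1 - M|`.
#' @param conf_extremity Confidence bonus per unit of squared (centered)
#'   second rating.
#' @param conf_noise_sd Report noise SD on the confidence link.
#' @param rating_center_range,rating_scale_range,conf_center_range,conf_scale_range
#'   Ranges for the jittered affine maps from latent z units to raw slider
#'   units.
#' @param seed Integer seed; every draw in the generator is governed by it.
#' @return Object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_participants = 18, n_products = 210,
                        review_count_meanlog = log(60),
                        review_count_sdlog = 1.3,
                        review_count_range = c(3, 2000),
                        star_mean = 4.0, star_sd = 0.6,
                        star_range = c(1, 5), star_within_sd = 1.0,
                        s2_low_range = c(0.35, 0.75),
                        s2_ratio_range = c(0.45, 0.85),
                        w_low_range = c(0.2, 0.9),
                        w_gap_range = c(0.3, 1.5),
                        conf_carryover = 0.5, conf_slope = 1,
                        conf_conflict = 0.4, conf_extremity = 0.3,
                        conf_noise_sd = 1,
                        rating_center_range = c(230, 270),
                        rating_scale_range = c(55, 75),
                        conf_center_range = c(230, 270),
                        conf_scale_range = c(40, 60),
                        seed = NULL) {
  spec <- list(n_participants = as.integer(n_participants),
               n_products = as.integer(n_products),
               review_count_meanlog = review_count_meanlog,
               review_count_sdlog = review_count_sdlog,
               review_count_range = review_count_range,
               star_mean = star_mean, star_sd = star_sd,
               star_range = star_range, star_within_sd = star_within_sd,
               s2_low_range = s2_low_range,
               s2_ratio_range = s2_ratio_range,
               w_low_range = w_low_range, w_gap_range = w_gap_range,
               conf_carryover = conf_carryover, conf_slope = conf_slope,
               conf_conflict = conf_conflict,
               conf_extremity = conf_extremity,
               conf_noise_sd = conf_noise_sd,
               rating_center_range = rating_center_range,
               rating_scale_range = rating_scale_range,
               conf_center_range = conf_center_range,
               conf_scale_range = conf_scale_range,
               seed = seed)
  stopifnot(spec$n_participants >= 1, spec$n_products >= 1,
            spec$review_count_range[1] >= 1,
            diff(spec$review_count_range) >= 0,
            diff(spec$star_range) >= 0, spec$star_within_sd > 0,
            diff(spec$s2_low_range) >= 0, spec$s2_low_range[1] > 0,
            diff(spec$s2_ratio_range) >= 0,
            spec$s2_ratio_range[1] > 0, spec$s2_ratio_range[2] <= 1,
            diff(spec$w_low_range) >= 0, spec$w_low_range[1] >= 0,
            diff(spec$w_gap_range) >= 0, spec$w_gap_range[1] >= 0,
            spec$conf_noise_sd >= 0)
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d participants x %d products (seed: %s)\n",
              x$n_participants, x$n_products,
              if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  reviews: counts ~ logN(%.2f, %.2f) in [%g, %g]; stars ~ truncN(%.1f, %.1f)\n",
              x$review_count_meanlog, x$review_count_sdlog,
              x$review_count_range[1], x$review_count_range[2],
              x$star_mean, x$star_sd))
  cat(sprintf("  priors: s2_low ~ U[%.2f, %.2f], ratio ~ U[%.2f, %.2f]; w_low ~ U[%.2f, %.2f], gap ~ U[%.2f, %.2f]\n",
              x$s2_low_range[1], x$s2_low_range[2],
              x$s2_ratio_range[1], x$s2_ratio_range[2],
              x$w_low_range[1], x$w_low_range[2],
              x$w_gap_range[1], x$w_gap_range[2]))
  invisible(x)
}

# Star-histogram bin probabilities with mean pinned exactly to m: normal
# base weights at bin centers 1..5, exponentially tilted so the bin-center
# mean equals m. Keeps the drawn histogram an unbiased sample around m.
.star_probs <- function(m, within_sd) {
  m <- min(max(m, 1.01), 4.99)
  base <- stats::dnorm(1:5, m, within_sd)
  f <- function(lam) {
    p <- base * exp(lam * (1:5))
    sum((1:5) * p) / sum(p) - m
  }
  lam <- stats::uniroot(f, c(-40, 40), tol = 1e-12)$root
  p <- base * exp(lam * (1:5))
  p / sum(p)
}

#' Simulate product review summaries
#'
#' Draws a reviewer count (log-normal, clamped) and a target star mean
#' (truncated normal) per product, then draws the 5-bin histogram
#' multinomially with bin probabilities tilted so their mean equals the
#' target; `mean_stars` is recomputed from the drawn histogram, so the
#' histogram invariants hold exactly.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed (defaults to `spec$seed`).
#' @return Review-summary data frame: `product_id`, `mean_stars`,
#'   `n_reviews`, `hist_1`..`hist_5`.
#' @export
simulate_reviews <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  local_seed(seed)
  n <- spec$n_products
  counts <- round(stats::rlnorm(n, spec$review_count_meanlog,
                                spec$review_count_sdlog))
  counts <- pmin(pmax(counts, spec$review_count_range[1]),
                 spec$review_count_range[2])
  target <- rtruncnorm(n, spec$star_mean, spec$star_sd,
                       spec$star_range[1], spec$star_range[2])
  hist <- matrix(0L, n, 5)
  for (j in seq_len(n)) {
    p <- .star_probs(target[j], spec$star_within_sd)
    hist[j, ] <- as.integer(stats::rmultinom(1, counts[j], p))
  }
  data.frame(product_id = sprintf("prod%03d", seq_len(n)),
             mean_stars = as.vector(hist %*% (1:5)) / counts,
             n_reviews = as.integer(counts),
             hist_1 = hist[, 1], hist_2 = hist[, 2], hist_3 = hist[, 3],
             hist_4 = hist[, 4], hist_5 = hist[, 5],
             stringsAsFactors = FALSE)
}

#' Simulate one participant's two-phase ratings
#'
#' Implements the model's own generative story on the latent (z) scale, then
#' maps the four judgment columns onto the raw 0-500 slider through the
#' participant's jittered affine maps:
#' initial confidence is a standard-normal latent whose per-participant
#' median split selects the prior variance actually used; the first rating is
#' drawn from the prior; the posterior combines the prior with the review
#' mean (on the participant's scale) weighted by the true review precision
#' for the trial's reviewer-count flag; the second rating is drawn from the
#' posterior; and second confidence follows the confidence link in
#' [cohort_spec()].
#'
#' @param spec A [cohort_spec()].
#' @param reviews Review summaries from [simulate_reviews()].
#' @param true_params A [participant_params()] covering all products.
#' @param participant_id Identifier written into the output.
#' @param seed Optional seed.
#' @return List with `trials` (raw CSV schema) and `latent` (the same trials
#'   on the generator's latent scale, columns named as [prepare_trials()]
#'   output: `r1`, `c1`, `r2`, `c2`, `m_std`, `high_conf`, `many_reviews`,
#'   plus `mu_true`).
#' @export
simulate_participant <- function(spec, reviews, true_params,
                                 participant_id = "p01", seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(true_params, "participant_params"))
  local_seed(seed)
  n <- nrow(reviews)
  pid <- as.character(reviews$product_id)
  mu <- true_params$prior_means[pid]
  if (any(is.na(mu))) {
    stop("simulate_participant: true_params must cover all products")
  }
  many <- as.integer(reviews$n_reviews > stats::median(reviews$n_reviews))

  # affine slider maps (drawn first so the draw order is stable)
  ctr_r1 <- stats::runif(1, spec$rating_center_range[1], spec$rating_center_range[2])
  scl_r1 <- stats::runif(1, spec$rating_scale_range[1], spec$rating_scale_range[2])
  ctr_r2 <- stats::runif(1, spec$rating_center_range[1], spec$rating_center_range[2])
  scl_r2 <- stats::runif(1, spec$rating_scale_range[1], spec$rating_scale_range[2])
  ctr_c1 <- stats::runif(1, spec$conf_center_range[1], spec$conf_center_range[2])
  scl_c1 <- stats::runif(1, spec$conf_scale_range[1], spec$conf_scale_range[2])
  ctr_c2 <- stats::runif(1, spec$conf_center_range[1], spec$conf_center_range[2])
  scl_c2 <- stats::runif(1, spec$conf_scale_range[1], spec$conf_scale_range[2])

  c1 <- stats::rnorm(n)
  high <- as.integer(c1 > stats::median(c1))
  s2 <- ifelse(high == 1, true_params$s2_high, true_params$s2_low)
  r1 <- mu + sqrt(s2) * stats::rnorm(n)

  m_raw <- (reviews$mean_stars - 1) / 4 * 500
  m_lat <- (m_raw - ctr_r1) / scl_r1
  w <- ifelse(many == 1, true_params$w_high, true_params$w_low)
  post_prec <- 1 / s2 + w
  post_mean <- (mu / s2 + w * m_lat) / post_prec
  r2 <- post_mean + stats::rnorm(n) / sqrt(post_prec)

  c2 <- spec$conf_carryover * c1 +
    spec$conf_slope * log(post_prec) -
    spec$conf_conflict * abs(r1 - m_lat) +
    spec$conf_extremity * (r2 - mean(r2))^2 +
    spec$conf_noise_sd * stats::rnorm(n)

  clip <- function(x) pmin(pmax(x, 0), 500)
  trials <- data.frame(
    participant_id = participant_id, product_id = pid,
    r1_raw = clip(ctr_r1 + scl_r1 * r1),
    c1_raw = clip(ctr_c1 + scl_c1 * c1),
    r2_raw = clip(ctr_r2 + scl_r2 * r2),
    c2_raw = clip(ctr_c2 + scl_c2 * c2),
    stringsAsFactors = FALSE)
  latent <- data.frame(
    participant_id = participant_id, product_id = pid,
    r1 = unname(r1), c1 = c1, r2 = unname(r2), c2 = c2,
    m_std = m_lat, high_conf = high, many_reviews = many,
    mu_true = unname(mu),
    stringsAsFactors = FALSE)
  list(trials = trials, latent = latent)
}

#' Simulate a full cohort
#'
#' Draws each participant's structural parameters from the intervals in the
#' spec, product prior means i.i.d. standard normal on the latent scale, and
#' two-phase ratings via [simulate_participant()]. Returns everything needed
#' for end-to-end runs and for parameter-recovery scoring.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `cohort_sim`: `trials` (raw schema, all
#'   participants), `reviews`, `true_params` (one row per participant, latent
#'   scale), `latent` (model-scale trials incl. true prior means), `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  local_seed(spec$seed)
  reviews <- simulate_reviews(spec, seed = NULL)  # continue the RNG stream
  ids <- sprintf("p%02d", seq_len(spec$n_participants))
  s2_low <- stats::runif(spec$n_participants, spec$s2_low_range[1],
                         spec$s2_low_range[2])
  s2_high <- s2_low * stats::runif(spec$n_participants,
                                   spec$s2_ratio_range[1],
                                   spec$s2_ratio_range[2])
  w_low <- stats::runif(spec$n_participants, spec$w_low_range[1],
                        spec$w_low_range[2])
  w_high <- w_low + stats::runif(spec$n_participants, spec$w_gap_range[1],
                                 spec$w_gap_range[2])
  trials <- vector("list", spec$n_participants)
  latent <- vector("list", spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    mu <- stats::rnorm(spec$n_products)
    names(mu) <- as.character(reviews$product_id)
    tp <- participant_params(mu, s2_low[i], s2_high[i], w_low[i], w_high[i])
    sim <- simulate_participant(spec, reviews, tp,
                                participant_id = ids[i], seed = NULL)
    trials[[i]] <- sim$trials
    latent[[i]] <- sim$latent
  }
  structure(list(
    trials = do.call(rbind, trials),
    reviews = reviews,
    true_params = data.frame(participant_id = ids, s2_low = s2_low,
                             s2_high = s2_high, w_low = w_low,
                             w_high = w_high, stringsAsFactors = FALSE),
    latent = do.call(rbind, latent),
    spec = spec
  ), class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants x %d products = %d trials\n",
              x$spec$n_participants, x$spec$n_products, nrow(x$trials)))
  cat(sprintf("  reviewer counts: %d-%d (median %g); star means: %.2f-%.2f\n",
              min(x$reviews$n_reviews), max(x$reviews$n_reviews),
              stats::median(x$reviews$n_reviews),
              min(x$reviews$mean_stars), max(x$reviews$mean_stars)))
  invisible(x)
}
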
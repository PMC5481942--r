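# Per-participant model parameters and per-trial derived measures.

#' Participant model parameters
#'
#' The per-participant parameters of the belief-updating model: one prior mean
#' per product, two prior variances (low- and high-confidence trials, with the
#' high-confidence variance no larger than the low-confidence one), and two
#' perceived review precisions (few- and many-review trials, with the
#' many-review precision at least as large).
#'
#' The underlying behavioral parameterization has a base prior variance plus a
#' nonpositive offset applied on high-confidence trials, and a perceived
#' review count (base count plus a non-negative increment when the reviewer
#' count is above the stimulus-set median) divided by a perceived review
#' variance. Only the two prior variances and the two count/variance ratios
#' are identifiable from ratings, so those four quantities are what is stored;
#' the perceived review variance is fixed to 1 for reporting.
#'
#' @param prior_means Named numeric vector of prior means, names are product
#'   ids.
#' @param s2_low Prior variance on low-confidence trials (> 0).
#' @param s2_high Prior variance on high-confidence trials
#'   (0 < `s2_high` <= `s2_low`).
#' @param w_low Perceived review precision when the product has few reviews
#'   (>= 0).
#' @param w_high Perceived review precision when the product has many reviews
#'   (`w_high` >= `w_low`).
#' @return An object of class `participant_params`.
#' @export
participant_params <- function(prior_means, s2_low, s2_high, w_low, w_high) {
  if (is.null(names(prior_means)) || any(!nzchar(names(prior_means)))) {
    stop("participant_params: prior_means must be named by product id")
  }
  stopifnot(length(s2_low) == 1L, length(s2_high) == 1L,
            length(w_low) == 1L, length(w_high) == 1L)
  if (!is.finite(s2_low) || !is.finite(s2_high) || s2_high <= 0) {
    stop("participant_params: prior variances must be finite and positive")
  }
  if (s2_high > s2_low + 1e-12) {
    stop("participant_params: s2_high must not exceed s2_low ",
         "(higher confidence cannot mean a wider prior)")
  }
  if (w_low < 0 || w_high < w_low - 1e-12) {
    stop("participant_params: need 0 <= w_low <= w_high")
  }
  structure(list(prior_means = prior_means,
                 s2_low = as.numeric(s2_low), s2_high = as.numeric(s2_high),
                 w_low = as.numeric(w_low), w_high = as.numeric(w_high),
                 tau2_report = 1),
            class = "participant_params")
}

#' @export
print.participant_params <- function(x, ...) {
  cat(sprintf(paste0("Participant parameters: %d prior means; ",
                     "s2 (low/high conf) = %.3g/%.3g; ",
                     "w (few/many reviews) = %.3g/%.3g\n"),
              length(x$prior_means), x$s2_low, x$s2_high, x$w_low, x$w_high))
  invisible(x)
}

#' Per-trial prior belief
#'
#' Looks up the prior for each trial: the product-specific prior mean, with
#' the high-confidence variance on trials where initial confidence was above
#' the participant's median and the low-confidence variance otherwise.
#'
#' @param params A [participant_params()].
#' @param trials Data frame with columns `product_id` and `high_conf` (0/1).
#' @return A [gaussian_belief()] with one element per trial.
#' @export
prior_for_trial <- function(params, trials) {
  stopifnot(inherits(params, "participant_params"))
  pid <- as.character(trials$product_id)
  missing <- setdiff(pid, names(params$prior_means))
  if (length(missing)) {
    stop("prior_for_trial: no prior mean for product(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  mu <- unname(params$prior_means[pid])
  s2 <- ifelse(trials$high_conf == 1, params$s2_high, params$s2_low)
  gaussian_belief(mu, s2)
}

#' Per-trial review likelihood
#'
#' The perceived review evidence for each trial: mean equal to the review mean
#' on the participant's standardized rating scale, precision equal to the
#' many-review precision when the reviewer count is above the stimulus-set
#' median and the few-review precision otherwise.
#'
#' @param params A [participant_params()].
#' @param trials Data frame with columns `m_std` and `many_reviews` (0/1).
#' @return List with numeric fields `mean` and `precision`.
#' @export
likelihood_for_trial <- function(params, trials) {
  stopifnot(inherits(params, "participant_params"))
  list(mean = trials$m_std,
       precision = ifelse(trials$many_reviews == 1,
                          params$w_high, params$w_low))
}

#' Trial log-likelihood under the belief-updating model
#'
#' The generative story scores each trial by the log density of the first
#' rating under the prior plus the log density of the second rating under the
#' conjugate posterior. Summed over trials this is the participant's fit
#' objective.
#'
#' @param params A [participant_params()].
#' @param trials Data frame with standardized columns `r1`, `r2`, `m_std` and
#'   flags `high_conf`, `many_reviews`, plus `product_id`.
#' @return Numeric vector of per-trial log-likelihood contributions (nats);
#'   `sum()` it for the participant objective.
#' @export
trial_loglik <- function(params, trials) {
  prior <- prior_for_trial(params, trials)
  lik <- likelihood_for_trial(params, trials)
  post <- posterior_update(prior, lik$mean, lik$precision)
  stats::dnorm(trials$r1, prior$mean, sqrt(prior$variance), log = TRUE) +
    stats::dnorm(trials$r2, post$mean, sqrt(post$variance), log = TRUE)
}

#' Derive per-trial model quantities
#'
#' For each trial, computes the prior, the review likelihood, the conjugate
#' posterior, the KL divergence from prior to posterior (the magnitude of
#' belief update), and the resistance weight (the share of the posterior mean
#' contributed by the prior).
#'
#' @param object A [participant_params()] or a fitted [fit_belief_model()]
#'   object.
#' @param trials For the `participant_params` method, the participant's
#'   trials; ignored for `belief_fit` (the training trials are used).
#' @param ... Unused.
#' @return Data frame with one row per trial: identifiers, prior mean and
#'   variance, likelihood mean and precision, posterior mean and variance,
#'   `kl` (nats) and `resistance` (in `[0,1]`).
#' @export
derive_trials <- function(object, ...) UseMethod("derive_trials")

#' @rdname derive_trials
#' @export
derive_trials.participant_params <- function(object, trials, ...) {
  prior <- prior_for_trial(object, trials)
  lik <- likelihood_for_trial(object, trials)
  post <- posterior_update(prior, lik$mean, lik$precision)
  data.frame(
    participant_id = trials$participant_id,
    product_id = trials$product_id,
    prior_mean = prior$mean,
    prior_var = prior$variance,
    likelihood_mean = lik$mean,
    likelihood_precision = lik$precision,
    post_mean = post$mean,
    post_var = post$variance,
    kl = kl_divergence(prior, post),
    resistance = resistance_weight(precision(prior), lik$precision),
    stringsAsFactors = FALSE
  )
}
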
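# Gaussian beliefs and the conjugate-update primitives of the model.

# Variances below this floor are lifted before any division; well below the
# resolution of standardized behavioral ratings.
.VAR_FLOOR <- 1e-8

#' Gaussian belief
#'
#' A belief about a product's value on the standardized rating scale,
#' represented as a Gaussian with a mean and a strictly positive variance.
#' Used for priors, perceived review likelihoods, and posteriors. Fields may
#' be vectors of equal length, in which case the object holds one belief per
#' element.
#'
#' @param mean Numeric vector of belief means (standardized rating units).
#' @param variance Numeric vector of strictly positive variances.
#' @return An object of class `gaussian_belief` with fields `mean` and
#'   `variance`; `precision(b)` gives `1/variance`.
#' @examples
#' b <- gaussian_belief(0.3, 1.2)
#' precision(b)
#' @export
gaussian_belief <- function(mean, variance) {
  mean <- as.numeric(mean)
  variance <- as.numeric(variance)
  if (length(mean) != length(variance)) {
    n <- max(length(mean), length(variance))
    mean <- rep_len(mean, n)
    variance <- rep_len(variance, n)
  }
  if (any(!is.finite(mean)) || any(!is.finite(variance))) {
    stop("gaussian_belief: mean and variance must be finite")
  }
  if (any(variance <= 0)) {
    stop("gaussian_belief: variance must be strictly positive")
  }
  structure(list(mean = mean, variance = variance), class = "gaussian_belief")
}

#' @rdname gaussian_belief
#' @param b A `gaussian_belief`.
#' @export
precision <- function(b) {
  stopifnot(inherits(b, "gaussian_belief"))
  1 / pmax(b$variance, .VAR_FLOOR)
}

#' @export
print.gaussian_belief <- function(x, ...) {
  n <- length(x$mean)
  if (n == 1L) {
    cat(sprintf("Gaussian belief: N(mean = %.4g, var = %.4g)\n",
                x$mean, x$variance))
  } else {
    cat(sprintf("Gaussian beliefs (n = %d):\n", n))
    print(utils::head(data.frame(mean = x$mean, variance = x$variance), 6L))
    if (n > 6L) cat("  ...\n")
  }
  invisible(x)
}

#' @export
length.gaussian_belief <- function(x) length(x$mean)

#' Conjugate Gaussian posterior update
#'
#' Combines a Gaussian prior with Gaussian evidence of known precision. The
#' posterior precision is the sum of the prior and likelihood precisions, and
#' the posterior mean is the precision-weighted average of the prior mean and
#' the evidence mean. With zero likelihood precision the posterior equals the
#' prior.
#'
#' @param prior A [gaussian_belief()].
#' @param likelihood_mean Evidence mean (the review mean on the standardized
#'   rating scale).
#' @param likelihood_precision Non-negative evidence precision.
#' @return A `gaussian_belief` posterior.
#' @examples
#' posterior_update(gaussian_belief(0, 1), likelihood_mean = 1,
#'                  likelihood_precision = 1)  # N(0.5, 0.5)
#' @export
posterior_update <- function(prior, likelihood_mean, likelihood_precision) {
  stopifnot(inherits(prior, "gaussian_belief"))
  if (any(likelihood_precision < 0)) {
    stop("posterior_update: likelihood_precision must be non-negative")
  }
  n <- max(length(prior$mean), length(likelihood_mean),
           length(likelihood_precision))
  pm <- rep_len(prior$mean, n)
  pv <- rep_len(prior$variance, n)
  lm <- rep_len(likelihood_mean, n)
  lp <- rep_len(likelihood_precision, n)
  pp <- 1 / pmax(pv, .VAR_FLOOR)
  post_prec <- pp + lp
  post_mean <- (pm * pp + lm * lp) / post_prec
  post_var <- 1 / post_prec
  # zero evidence precision is an exact identity, not a float round-trip
  zero <- lp == 0
  post_mean[zero] <- pm[zero]
  post_var[zero] <- pv[zero]
  gaussian_belief(post_mean, post_var)
}

#' Kullback-Leibler divergence from prior to posterior
#'
#' Closed-form KL divergence `KL(p || q)` between Gaussian beliefs, with `p`
#' the prior and `q` the posterior:
#' `log(sd_q/sd_p) + (var_p + (mean_p - mean_q)^2) / (2 var_q) - 1/2`,
#' in nats. This is the trial-wise magnitude of belief update: zero when the
#' beliefs coincide, strictly positive otherwise.
#'
#' @param prior,posterior [gaussian_belief()] objects (vectorized).
#' @return Non-negative numeric vector of divergences in nats.
#' @examples
#' kl_divergence(gaussian_belief(0, 1), gaussian_belief(1, 1))  # 0.5
#' @export
kl_divergence <- function(prior, posterior) {
  stopifnot(inherits(prior, "gaussian_belief"),
            inherits(posterior, "gaussian_belief"))
  vp <- pmax(prior$variance, .VAR_FLOOR)
  vq <- pmax(posterior$variance, .VAR_FLOOR)
  kl <- 0.5 * log(vq / vp) + (vp + (prior$mean - posterior$mean)^2) /
    (2 * vq) - 0.5
  # guard tiny negative round-off when the beliefs coincide
  pmax(kl, 0)
}

#' Resistance to social information
#'
#' The Bayesian weight of the prior mean in the posterior mean:
#' `prior_precision / (prior_precision + review_precision)`. Equal to 1 when
#' the reviews carry no weight (the posterior mean equals the prior mean) and
#' tends to 0 as the prior precision vanishes relative to the review precision
#' (the posterior mean equals the review mean).
#'
#' @param prior_precision Strictly positive prior precision(s).
#' @param review_precision Non-negative perceived review precision(s).
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' resistance_weight(1, 0)    # reviews ignored -> 1
#' resistance_weight(1e-6, 1) # prior discarded -> ~0
#' @export
resistance_weight <- function(prior_precision, review_precision) {
  if (any(prior_precision <= 0)) {
    stop("resistance_weight: prior_precision must be strictly positive")
  }
  if (any(review_precision < 0)) {
    stop("resistance_weight: review_precision must be non-negative")
  }
  prior_precision / (prior_precision + review_precision)
}

#' Participant-level resistance
#'
#' Arithmetic mean of per-trial resistance weights across a participant's
#' products.
#'
#' @param resistance Numeric vector of per-trial resistance values in `[0,1]`,
#'   or a data frame with a `resistance` column (as returned by
#'   [derive_trials()]).
#' @return A single number in `[0, 1]`.
#' @export
participant_resistance <- function(resistance) {
  if (is.data.frame(resistance)) resistance <- resistance$resistance
  if (length(resistance) < 1L) {
    stop("participant_resistance: needs at least one trial")
  }
  mean(resistance)
}
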
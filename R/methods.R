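# S3 methods for the cohort fit object.

#' @export
print.belief_fit <- function(x, ...) {
  cat("Belief-updating model fit\n")
  cat(sprintf("  %d participants, %d trials, %d restarts per participant\n",
              nrow(x$params), nrow(x$trials), x$n_restarts))
  cat(sprintf("  total logLik: %.2f\n", sum(x$params$loglik)))
  cat(sprintf("  mean cor(prior mean, R1): %.3f\n",
              mean(x$params$corr_prior_r1)))
  cat(sprintf("  mean cor(posterior mean, R2): %.3f\n",
              mean(x$params$corr_post_r2)))
  cat(sprintf("  mean resistance to reviews: %.3f\n",
              mean(x$params$mean_resistance)))
  nz <- sum(x$params$zero_weight)
  if (nz > 0) {
    cat(sprintf("  %d participant(s) with ~zero fitted review weight\n", nz))
  }
  invisible(x)
}

#' @export
summary.belief_fit <- function(object, ...) {
  structure(list(params = object$params,
                 n_trials = nrow(object$trials),
                 mean_corr_prior_r1 = mean(object$params$corr_prior_r1),
                 mean_corr_post_r2 = mean(object$params$corr_post_r2),
                 mean_resistance = mean(object$params$mean_resistance),
                 mean_kl = mean(object$derived$kl)),
            class = "summary.belief_fit")
}

#' @export
print.summary.belief_fit <- function(x, ...) {
  cat("Belief-updating model: participant-level estimates\n\n")
  print(x$params, digits = 3, row.names = FALSE)
  cat(sprintf("\nMean fit quality: cor(prior, R1) = %.3f, cor(post, R2) = %.3f\n",
              x$mean_corr_prior_r1, x$mean_corr_post_r2))
  cat(sprintf("Mean KL divergence per trial: %.4f nats\n", x$mean_kl))
  cat(sprintf("Mean resistance to reviews: %.3f\n", x$mean_resistance))
  invisible(x)
}

#' @export
coef.belief_fit <- function(object, ...) {
  m <- as.matrix(object$params[, c("s2_low", "s2_high", "w_low", "w_high")])
  rownames(m) <- object$params$participant_id
  m
}

#' @export
logLik.belief_fit <- function(object, ...) {
  val <- sum(object$params$loglik)
  # 4 structural parameters plus one profiled prior mean per trial
  df <- 4L * nrow(object$params) + nrow(object$trials)
  structure(val, df = df, nobs = 2L * nrow(object$trials), class = "logLik")
}

#' @export
fitted.belief_fit <- function(object, ...) object$derived$post_mean

#' @export
residuals.belief_fit <- function(object, ...) {
  object$trials$r2 - object$derived$post_mean
}

#' Predict posterior means for (new) trials
#'
#' Applies each participant's fitted parameters to a prepared trial table and
#' returns the posterior mean per trial. Products must have been seen in the
#' fit (the prior mean is product-specific).
#'
#' @param object A `belief_fit`.
#' @param newdata Prepared trial table; defaults to the training trials.
#' @param ... Unused.
#' @return Numeric vector of posterior means.
#' @export
predict.belief_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  out <- numeric(nrow(newdata))
  for (id in unique(newdata$participant_id)) {
    if (!id %in% names(object$fits)) {
      stop("predict.belief_fit: unknown participant ", id)
    }
    idx <- newdata$participant_id == id
    d <- derive_trials(object$fits[[id]]$params,
                       newdata[idx, , drop = FALSE])
    out[idx] <- d$post_mean
  }
  out
}

#' Simulate ratings from a fitted model
#'
#' Draws standardized first ratings from each trial's fitted prior and second
#' ratings from its fitted posterior — the model's own generative story — for
#' posterior-predictive style checks.
#'
#' @param object A `belief_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed; caller RNG state restored.
#' @param ... Unused.
#' @return A data frame with columns `sim`, `participant_id`, `product_id`,
#'   `r1`, `r2`.
#' @export
simulate.belief_fit <- function(object, nsim = 1, seed = NULL, ...) {
  local_seed(seed)
  d <- object$derived
  n <- nrow(d)
  out <- lapply(seq_len(nsim), function(s) {
    data.frame(sim = s,
               participant_id = d$participant_id,
               product_id = d$product_id,
               r1 = stats::rnorm(n, d$prior_mean, sqrt(d$prior_var)),
               r2 = stats::rnorm(n, d$post_mean, sqrt(d$post_var)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit-quality plot
#'
#' Two scatter panels: fitted prior means against observed first ratings and
#' model posterior means against observed second ratings, pooled over
#' participants, with the identity line.
#'
#' @param x A `belief_fit`.
#' @param ... Passed to `plot()`.
#' @export
plot.belief_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$derived$prior_mean, x$trials$r1,
                 xlab = "fitted prior mean", ylab = "first rating (z)",
                 pch = 16, cex = 0.4, col = "#00000055", ...)
  graphics::abline(0, 1, col = "red3")
  graphics::plot(x$derived$post_mean, x$trials$r2,
                 xlab = "posterior mean", ylab = "second rating (z)",
                 pch = 16, cex = 0.4, col = "#00000055", ...)
  graphics::abline(0, 1, col = "red3")
  invisible(x)
}
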
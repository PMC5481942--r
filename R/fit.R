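# Per-participant maximum-likelihood fitting, with the product-level prior
# means profiled out in closed form at every objective evaluation.

#' Closed-form profiled prior mean
#'
#' For fixed structural parameters, the trial's contribution to the
#' log-likelihood is `log N(r1; mu, s2) + log N(r2; a*mu + (1-a)*m_std, 1/P)`
#' with `P = 1/s2 + w` and `a = (1/s2)/P`. This is quadratic in `mu`, so the
#' maximizing prior mean is unique and available in closed form:
#' `mu* = (r1 + r2 - (1-a) m_std) / (1 + a)`.
#' With `w = 0` (so `a = 1`) this reduces to `(r1 + r2)/2`.
#'
#' @param s2 Prior variance(s) in force on the trial (> 0).
#' @param w Perceived review precision(s) in force on the trial (>= 0).
#' @param m_std Review mean on the standardized scale.
#' @param r1,r2 Standardized first and second ratings.
#' @return The profiled prior mean(s), vectorized over trials.
#' @export
profile_prior_mean <- function(s2, w, m_std, r1, r2) {
  stopifnot(all(s2 > 0), all(w >= 0))
  p0 <- 1 / s2
  a <- p0 / (p0 + w)
  (r1 + r2 - (1 - a) * m_std) / (1 + a)
}

# Negative profiled log-likelihood in the unconstrained parameterization
# theta = (log s2_high, log(s2_low - s2_high), log w_low, log(w_high - w_low)).
# The order constraints s2_high <= s2_low and w_low <= w_high hold by
# construction; gaps and w_low may be driven arbitrarily close to zero.
.theta_to_params <- function(theta) {
  s2_high <- exp(theta[1])
  s2_low <- s2_high + exp(theta[2])
  w_low <- exp(theta[3])
  w_high <- w_low + exp(theta[4])
  c(s2_low = s2_low, s2_high = s2_high, w_low = w_low, w_high = w_high)
}

.make_nll <- function(r1, r2, m, hc, mr) {
  function(theta) {
    if (any(!is.finite(theta)) || any(theta > 50)) return(1e10)
    p <- .theta_to_params(theta)
    s2 <- pmax(ifelse(hc == 1, p[["s2_high"]], p[["s2_low"]]), .VAR_FLOOR)
    w <- ifelse(mr == 1, p[["w_high"]], p[["w_low"]])
    p0 <- 1 / s2
    P <- p0 + w
    a <- p0 / P
    mu <- (r1 + r2 - (1 - a) * m) / (1 + a)
    pm <- a * mu + (1 - a) * m
    ll <- sum(stats::dnorm(r1, mu, sqrt(s2), log = TRUE) +
                stats::dnorm(r2, pm, sqrt(1 / P), log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
  }
}

#' Fit the belief-updating model to one participant
#'
#' Maximizes the participant's total log-likelihood over the four structural
#' parameters (`s2_low`, `s2_high`, `w_low`, `w_high`) by multi-start
#' unconstrained optimization on a log/log-gap scale (so the order constraints
#' hold by construction), profiling every product-level prior mean in closed
#' form at each objective evaluation. Each restart runs Nelder-Mead followed
#' by a BFGS polish; the best restart is kept. Fitted review precisions below
#' `1e-6` are snapped to exactly 0.
#'
#' @param trials One participant's prepared trials (see [prepare_trials()]):
#'   columns `r1`, `r2`, `m_std`, `high_conf`, `many_reviews`, `product_id`
#'   (and `c2` if the precision-confidence check is wanted later).
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Optional seed for the restart draws; RNG state is restored on
#'   exit.
#' @param reltol Convergence tolerance on the objective.
#' @param cor_method Correlation type for the fit-quality diagnostics
#'   (`"pearson"` default, `"spearman"` available).
#' @param df_correct Apply the degrees-of-freedom correction for the
#'   incidental prior means (default `TRUE`). Profiling one prior mean per
#'   trial leaves a single residual degree of freedom for the two
#'   observations of each trial, so the raw profile-ML shrinks every
#'   variance-scale parameter toward exactly half its consistent value as the
#'   number of trials grows, while leaving the precision weights, the
#'   profiled means, the posterior means, the resistance index and the
#'   fit-quality correlations untouched. The correction doubles the fitted
#'   prior variances and halves the fitted review precisions; set
#'   `df_correct = FALSE` for the uncorrected profile-ML.
#' @return An object of class `participant_fit`: fitted
#'   [participant_params()], `loglik` (at the reported parameters),
#'   `profile_loglik` (the maximized profile-ML objective), `n_trials`,
#'   `converged`,
#'   `n_restarts_used`, `restart_logliks`, the fit-quality correlations
#'   `corr_prior_r1` (fitted prior means vs first ratings) and `corr_post_r2`
#'   (posterior means vs second ratings), and `zero_weight` (TRUE when both
#'   fitted review precisions are below 0.05, mirroring participants for whom
#'   the update magnitude is numerically zero on many trials).
#' @export
fit_participant <- function(trials, n_restarts = 10, seed = NULL,
                            reltol = 1e-10,
                            cor_method = c("pearson", "spearman"),
                            df_correct = TRUE) {
  cor_method <- match.arg(cor_method)
  local_seed(seed)
  need <- c("r1", "r2", "m_std", "high_conf", "many_reviews", "product_id")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("fit_participant: trials lack column(s): ",
         paste(missing, collapse = ", "), "; run prepare_trials() first")
  }
  cells <- table(factor(trials$high_conf, levels = 0:1),
                 factor(trials$many_reviews, levels = 0:1))
  if (any(cells < 2)) {
    warning("fit_participant: fewer than 2 trials in some ",
            "confidence x review-count cell; parameters for that cell are ",
            "weakly identified")
  }
  r1 <- trials$r1; r2 <- trials$r2; m <- trials$m_std
  hc <- trials$high_conf; mr <- trials$many_reviews
  nll <- .make_nll(r1, r2, m, hc, mr)

  best <- NULL
  restart_vals <- rep(NA_real_, n_restarts)
  n_ok <- 0L
  for (k in seq_len(n_restarts)) {
    # variances log-uniform in [0.1, 10]; precisions log-uniform in [0.01, 10]
    v <- sort(exp(stats::runif(2, log(0.1), log(10))))
    wv <- sort(exp(stats::runif(2, log(0.01), log(10))))
    theta0 <- c(log(v[1]), log(max(v[2] - v[1], 1e-4)),
                log(wv[1]), log(max(wv[2] - wv[1], 1e-4)))
    fit <- tryCatch({
      nm <- stats::optim(theta0, nll, method = "Nelder-Mead",
                         control = list(maxit = 800, reltol = reltol))
      stats::optim(nm$par, nll, method = "BFGS",
                   control = list(maxit = 200, reltol = reltol))
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    n_ok <- n_ok + 1L
    restart_vals[k] <- -fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("fit_participant: all ", n_restarts, " restarts failed ",
         "(n_trials = ", nrow(trials), ")")
  }

  p <- .theta_to_params(best$par)
  w_low <- if (p[["w_low"]] < 1e-6) 0 else p[["w_low"]]
  w_high <- if (p[["w_high"]] < 1e-6) 0 else p[["w_high"]]
  s2_high <- min(p[["s2_high"]], p[["s2_low"]])
  s2_low <- p[["s2_low"]]
  if (df_correct) {
    # one residual df per trial: variances up by 2, precisions down by 2;
    # weights a and the profiled means are invariant to this rescaling
    s2_low <- 2 * s2_low
    s2_high <- 2 * s2_high
    w_low <- w_low / 2
    w_high <- w_high / 2
  }
  mu <- profile_prior_mean(
    s2 = ifelse(hc == 1, s2_high, s2_low),
    w = ifelse(mr == 1, w_high, w_low),
    m_std = m, r1 = r1, r2 = r2)
  # one profiled mean per product (each product appears once per participant)
  prior_means <- mu
  names(prior_means) <- as.character(trials$product_id)
  params <- participant_params(prior_means, s2_low = s2_low,
                               s2_high = s2_high,
                               w_low = w_low, w_high = w_high)
  ll <- sum(trial_loglik(params, trials))
  post <- posterior_update(prior_for_trial(params, trials),
                           m, likelihood_for_trial(params, trials)$precision)
  structure(list(
    params = params,
    loglik = ll,
    profile_loglik = -best$value,
    n_trials = nrow(trials),
    converged = best$convergence == 0 && is.finite(ll),
    n_restarts_used = n_ok,
    restart_logliks = restart_vals,
    corr_prior_r1 = stats::cor(mu, r1, method = cor_method),
    corr_post_r2 = stats::cor(post$mean, r2, method = cor_method),
    zero_weight = (w_low < 0.05 && w_high < 0.05)
  ), class = "participant_fit")
}

#' @export
print.participant_fit <- function(x, ...) {
  cat(sprintf(paste0("Participant fit: %d trials, logLik = %.2f%s\n"),
              x$n_trials, x$loglik,
              if (x$zero_weight) " [zero review weight]" else ""))
  print(x$params)
  cat(sprintf("  fit quality: cor(prior mean, R1) = %.3f; ",
              x$corr_prior_r1))
  cat(sprintf("cor(posterior mean, R2) = %.3f\n", x$corr_post_r2))
  invisible(x)
}

#' Fit the belief-updating model to a cohort
#'
#' The main fitting entry point. Splits the prepared trial table by
#' participant, fits each participant independently by profile-likelihood
#' maximum likelihood (see [fit_participant()]), and assembles the per-trial
#' derived measures (prior, posterior, KL divergence, resistance).
#'
#' @param trials Prepared trial table from [prepare_trials()] (all
#'   participants).
#' @param n_restarts Random restarts per participant (default 10).
#' @param seed Optional integer; participant `i` is fitted with seed
#'   `seed + i`, and the caller-visible RNG state is untouched.
#' @param cor_method,df_correct Passed to [fit_participant()].
#' @return Object of class `belief_fit` with components `fits` (list of
#'   `participant_fit`), `params` (one-row-per-participant data frame of
#'   fitted parameters, log-likelihood, fit-quality correlations, mean
#'   resistance, flags), `derived` (per-trial data frame from
#'   [derive_trials()]), `trials`, and the call. Standard methods are
#'   available: `print`, `summary`, `coef`, `logLik`, `fitted`, `residuals`,
#'   `predict`, `simulate`, `plot`.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(cohort_spec(n_participants = 2, n_products = 40,
#'                                    seed = 7))
#' prep <- prepare_trials(sim$trials, sim$reviews)
#' fit <- fit_belief_model(prep, n_restarts = 3, seed = 7)
#' fit
#' }
#' @export
fit_belief_model <- function(trials, n_restarts = 10, seed = NULL,
                             cor_method = c("pearson", "spearman"),
                             df_correct = TRUE) {
  cor_method <- match.arg(cor_method)
  ids <- unique(trials$participant_id)
  fits <- vector("list", length(ids))
  names(fits) <- ids
  for (i in seq_along(ids)) {
    sub <- trials[trials$participant_id == ids[i], , drop = FALSE]
    fits[[i]] <- fit_participant(
      sub, n_restarts = n_restarts,
      seed = if (is.null(seed)) NULL else seed + i,
      cor_method = cor_method, df_correct = df_correct)
  }
  params <- do.call(rbind, lapply(seq_along(ids), function(i) {
    f <- fits[[i]]
    data.frame(participant_id = ids[i],
               s2_low = f$params$s2_low, s2_high = f$params$s2_high,
               w_low = f$params$w_low, w_high = f$params$w_high,
               loglik = f$loglik, n_trials = f$n_trials,
               corr_prior_r1 = f$corr_prior_r1,
               corr_post_r2 = f$corr_post_r2,
               converged = f$converged, zero_weight = f$zero_weight,
               stringsAsFactors = FALSE)
  }))
  derived <- do.call(rbind, lapply(ids, function(id) {
    derive_trials(fits[[id]]$params,
                  trials[trials$participant_id == id, , drop = FALSE])
  }))
  rownames(derived) <- NULL
  res_by_p <- tapply(derived$resistance, derived$participant_id, mean)
  params$mean_resistance <- unname(res_by_p[params$participant_id])
  structure(list(fits = fits, params = params, derived = derived,
                 trials = trials, n_restarts = n_restarts, seed = seed,
                 call = match.call()),
            class = "belief_fit")
}

#' @rdname derive_trials
#' @export
derive_trials.belief_fit <- function(object, ...) object$derived

#' Per-participant resistance from a cohort fit
#'
#' @param fit A [fit_belief_model()] object.
#' @return Named numeric vector: mean resistance per participant.
#' @export
resistance_by_participant <- function(fit) {
  stopifnot(inherits(fit, "belief_fit"))
  out <- tapply(fit$derived$resistance, fit$derived$participant_id, mean)
  out[unique(fit$trials$participant_id)]
}

#' Posterior-precision vs second-confidence check
#'
#' The model is never fitted to confidence, so an out-of-fit check is to
#' correlate its posterior precision with the participant's second confidence
#' rating: a Bayesian reporter should be more confident when the model says
#' the posterior is tighter.
#'
#' @param fit A [fit_belief_model()] object (its trials must carry `c2`).
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return Named numeric vector of per-participant correlations.
#' @export
precision_confidence <- function(fit, cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  stopifnot(inherits(fit, "belief_fit"))
  if (!"c2" %in% names(fit$trials)) {
    stop("precision_confidence: trials carry no c2 column")
  }
  ids <- unique(fit$trials$participant_id)
  out <- vapply(ids, function(id) {
    idx <- fit$trials$participant_id == id
    prec <- 1 / fit$derived$post_var[idx]
    c2 <- fit$trials$c2[idx]
    if (length(prec) < 3) stop("precision_confidence: fewer than 3 trials")
    if (stats::sd(prec) == 0 || stats::sd(c2) == 0) {
      stop("precision_confidence: zero variance for participant ", id)
    }
    stats::cor(prec, c2, method = cor_method)
  }, numeric(1))
  names(out) <- ids
  out
}
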
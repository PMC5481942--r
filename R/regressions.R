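# The behavioral regression battery: hierarchical (mixed-effects) models for
# the rating update, the confidence update, and the quadratic
# confidence-extremity relation, with 2-df likelihood-ratio tests that drop a
# focal fixed effect together with its participant-level random slope.

#' Build the regression design table
#'
#' Derives the analysis columns from a prepared trial table:
#' `update = r2 - r1` (rating update), `conf_update = c2 - c1` (confidence
#' update), `dev = m_std - r1` (initial deviation from the group consensus),
#' `abs_dev = |r1 - m_std|`, the median-split interactions
#' `dev_x_many = dev * many_reviews` and `dev_x_high = dev * high_conf`, and
#' `r2_sq = r2^2` (rating extremity).
#'
#' @param trials Prepared trial table (see [prepare_trials()]).
#' @return Data frame with the derived columns plus identifiers, flags, `r2`
#'   and `c2`.
#' @export
build_design <- function(trials) {
  need <- c("r1", "c1", "r2", "c2", "m_std", "high_conf", "many_reviews")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("build_design: trials lack column(s): ",
         paste(missing, collapse = ", "))
  }
  data.frame(
    participant_id = trials$participant_id,
    product_id = trials$product_id,
    update = trials$r2 - trials$r1,
    conf_update = trials$c2 - trials$c1,
    dev = trials$m_std - trials$r1,
    abs_dev = abs(trials$r1 - trials$m_std),
    dev_x_many = (trials$m_std - trials$r1) * trials$many_reviews,
    dev_x_high = (trials$m_std - trials$r1) * trials$high_conf,
    r2_sq = trials$r2^2,
    r2 = trials$r2,
    c2 = trials$c2,
    high_conf = trials$high_conf,
    many_reviews = trials$many_reviews,
    stringsAsFactors = FALSE
  )
}

# Fit response ~ fixed terms with random intercept and an optional
# uncorrelated random slope, by ML. Falls back to intercept-only random
# structure when the richer fit fails; the fallback is flagged.
.fit_lmm <- function(response, fixed, slope, data) {
  rhs <- paste(c("1", fixed), collapse = " + ")
  re <- "(1 | participant_id)"
  if (!is.null(slope)) {
    re <- paste(re, sprintf("+ (0 + %s | participant_id)", slope))
  }
  f <- stats::as.formula(paste(response, "~", rhs, "+", re))
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            optCtrl = list(maxfun = 1e5))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(f, data = data, REML = FALSE,
                                control = ctrl)),
    error = function(e) NULL)
  simplified <- FALSE
  if (is.null(fit) && !is.null(slope)) {
    f <- stats::as.formula(paste(response, "~", rhs,
                                 "+ (1 | participant_id)"))
    fit <- suppressMessages(lme4::lmer(f, data = data, REML = FALSE,
                                       control = ctrl))
    simplified <- TRUE
  }
  list(fit = fit, simplified = simplified)
}

.coef_table <- function(fit) {
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s),
             estimate = s[, "Estimate"],
             se = s[, "Std. Error"],
             ci_lo = s[, "Estimate"] - 1.96 * s[, "Std. Error"],
             ci_hi = s[, "Estimate"] + 1.96 * s[, "Std. Error"],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Likelihood-ratio test dropping the focal fixed effect together with its
# random-slope variance (2 df), both models fitted by ML.
.lrt_focal <- function(response, all_fixed, focal, data) {
  full <- .fit_lmm(response, all_fixed, slope = focal, data = data)
  red <- .fit_lmm(response, setdiff(all_fixed, focal), slope = NULL,
                  data = data)
  chisq <- max(0, 2 * (as.numeric(stats::logLik(full$fit)) -
                         as.numeric(stats::logLik(red$fit))))
  df <- 2L - as.integer(full$simplified)
  data.frame(term = focal, chisq = chisq, df = df,
             p = stats::pchisq(chisq, df, lower.tail = FALSE),
             simplified = full$simplified,
             stringsAsFactors = FALSE)
}

.new_reg_result <- function(label, fit, lrt, data, simplified) {
  structure(list(formula_label = label,
                 coefficients = .coef_table(fit),
                 lrt = lrt,
                 n_obs = nrow(data),
                 n_participants = length(unique(data$participant_id)),
                 simplified = simplified,
                 model = fit),
            class = "belief_reg")
}

#' Hierarchical regression of rating update
#'
#' Mixed-effects regression of the rating update (`r2 - r1`) on the initial
#' deviation from the group consensus and its median-split interactions with
#' reviewer count and initial confidence, with a participant-level random
#' intercept and an uncorrelated random slope for the deviation. For each
#' requested term a 2-df likelihood-ratio test is reported against the model
#' without that term's fixed effect and random-slope variance (ML fits).
#'
#' Under reliability-weighted integration the deviation coefficient is
#' positive (people move toward the consensus), the reviewer-count interaction
#' is positive (more so when the group is large), and the confidence
#' interaction is negative (less so when initially confident).
#'
#' @param design Table from [build_design()].
#' @param terms Fixed-effect terms to include and test.
#' @return A `belief_reg`: coefficient table (estimate, SE, 95% CI), LRT
#'   table (chi-square, df, p), and fit metadata.
#' @export
fit_update_model <- function(design,
                             terms = c("dev", "dev_x_many", "dev_x_high")) {
  if (length(unique(design$participant_id)) < 2) {
    stop("fit_update_model: needs >= 2 participants")
  }
  main <- .fit_lmm("update", terms, slope = "dev", design)
  lrt <- do.call(rbind, lapply(terms, function(t)
    .lrt_focal("update", terms, t, design)))
  .new_reg_result("update ~ dev + dev:many_reviews[ms] + dev:high_conf[ms]",
                  main$fit, lrt, design, main$simplified)
}

#' Hierarchical regressions for confidence
#'
#' Two mixed-effects regressions: the confidence update (`c2 - c1`) on the
#' absolute initial disagreement with the group (`|r1 - m_std|`; a negative
#' coefficient means disagreement with the consensus costs confidence), and
#' the second confidence rating on squared second rating (`r2^2`; a positive
#' coefficient means confidence is highest at the ends of the rating scale).
#' Same random-effects and 2-df LRT conventions as [fit_update_model()].
#'
#' @param design Table from [build_design()].
#' @return List with elements `conf_update` and `c2_quadratic`, each a
#'   `belief_reg`.
#' @export
fit_confidence_models <- function(design) {
  if (length(unique(design$participant_id)) < 2) {
    stop("fit_confidence_models: needs >= 2 participants")
  }
  m1 <- .fit_lmm("conf_update", "abs_dev", slope = "abs_dev", design)
  l1 <- .lrt_focal("conf_update", "abs_dev", "abs_dev", design)
  m2 <- .fit_lmm("c2", "r2_sq", slope = "r2_sq", design)
  l2 <- .lrt_focal("c2", "r2_sq", "r2_sq", design)
  list(
    conf_update = .new_reg_result("conf_update ~ abs_dev", m1$fit, l1,
                                  design, m1$simplified),
    c2_quadratic = .new_reg_result("c2 ~ r2_sq", m2$fit, l2,
                                   design, m2$simplified)
  )
}

#' @export
print.belief_reg <- function(x, ...) {
  cat("Hierarchical regression:", x$formula_label, "\n")
  cat(sprintf("  %d observations, %d participants%s\n", x$n_obs,
              x$n_participants,
              if (x$simplified) " [random slope dropped]" else ""))
  cat("\nFixed effects:\n")
  print(x$coefficients, digits = 3, row.names = FALSE)
  cat("\nLikelihood-ratio tests (focal fixed effect + random slope):\n")
  print(x$lrt, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Signature check for reliability-weighted integration
#'
#' Evaluates the five qualitative signatures on fitted regressions: positive
#' deviation effect on update, positive deviation-by-reviewer-count
#' interaction, negative deviation-by-confidence interaction, negative
#' absolute-disagreement effect on confidence update, and positive rating
#' extremity effect on second confidence.
#'
#' @param update_reg Result of [fit_update_model()].
#' @param conf_regs Result of [fit_confidence_models()].
#' @param alpha LRT p-value each effect must also beat (default 0.01).
#' @return Named logical vector of length 5; `all()` of it means the full
#'   pattern holds.
#' @export
signature_check <- function(update_reg, conf_regs, alpha = 0.01) {
  est <- function(reg, term) {
    reg$coefficients$estimate[reg$coefficients$term == term]
  }
  pval <- function(reg, term) reg$lrt$p[reg$lrt$term == term]
  c(
    dev_positive = est(update_reg, "dev") > 0 &&
      pval(update_reg, "dev") < alpha,
    dev_x_many_positive = est(update_reg, "dev_x_many") > 0 &&
      pval(update_reg, "dev_x_many") < alpha,
    dev_x_high_negative = est(update_reg, "dev_x_high") < 0 &&
      pval(update_reg, "dev_x_high") < alpha,
    abs_dev_negative = est(conf_regs$conf_update, "abs_dev") < 0 &&
      pval(conf_regs$conf_update, "abs_dev") < alpha,
    r2sq_positive = est(conf_regs$c2_quadratic, "r2_sq") > 0 &&
      pval(conf_regs$c2_quadratic, "r2_sq") < alpha
  )
}

#' Fixed-effects coefficient plot
#'
#' Point-and-interval plot of the fixed-effects estimates (95% CIs) from the
#' three behavioral regressions, one panel per response.
#'
#' @param update_reg Result of [fit_update_model()].
#' @param conf_regs Result of [fit_confidence_models()].
#' @export
plot_coefficients <- function(update_reg, conf_regs) {
  regs <- list("update (R2-R1)" = update_reg,
               "conf. update (C2-C1)" = conf_regs$conf_update,
               "confidence (C2)" = conf_regs$c2_quadratic)
  op <- graphics::par(mfrow = c(1, 3), mar = c(8, 4, 3, 1))
  on.exit(graphics::par(op))
  for (nm in names(regs)) {
    ct <- regs[[nm]]$coefficients
    ct <- ct[ct$term != "(Intercept)", , drop = FALSE]
    xs <- seq_len(nrow(ct))
    graphics::plot(xs, ct$estimate, ylim = range(c(ct$ci_lo, ct$ci_hi, 0)),
                   xlim = c(0.5, nrow(ct) + 0.5), xaxt = "n",
                   xlab = "", ylab = "fixed-effect estimate", main = nm,
                   pch = 16)
    graphics::arrows(xs, ct$ci_lo, xs, ct$ci_hi, angle = 90, code = 3,
                     length = 0.04)
    graphics::abline(h = 0, lty = 2, col = "grey50")
    graphics::axis(1, at = xs, labels = ct$term, las = 2, cex.axis = 0.9)
  }
  invisible(NULL)
}
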
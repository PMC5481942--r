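# Reading, validation and standardization of two-phase rating data.
#
# Expected file schema (CSV, UTF-8, "." decimal): one row per
# (participant, product) with raw slider ratings on [0, 500] and the review
# summary shown for that product.

.TRIAL_COLS <- c("participant_id", "product_id",
                 "r1_raw", "c1_raw", "r2_raw", "c2_raw")
.REVIEW_COLS <- c("product_id", "mean_stars", "n_reviews",
                  paste0("hist_", 1:5))
.JUDGMENT_COLS <- c(r1 = "r1_raw", c1 = "c1_raw", r2 = "r2_raw", c2 = "c2_raw")

#' Read a trials file
#'
#' Reads the delimited trials table (columns `participant_id`, `product_id`,
#' `r1_raw`, `c1_raw`, `r2_raw`, `c2_raw`, `mean_stars`, `n_reviews`,
#' `hist_1`..`hist_5`), validates it, and splits it into a trial table and a
#' per-product review-summary table (deduplicated by product).
#'
#' Validation: all required columns present; raw ratings within `[0, 500]`;
#' for every product the 5-bin star histogram sums to `n_reviews` and its
#' bin-center mean matches `mean_stars` within 0.05. Violations are aggregated
#' and reported together.
#'
#' @param path Path to a CSV file.
#' @return List with elements `trials` (data frame, one row per trial) and
#'   `reviews` (data frame, one row per product).
#' @seealso [write_trials()], [prepare_trials()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("read_trials: file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c(.TRIAL_COLS, setdiff(.REVIEW_COLS, "product_id"))
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("read_trials: missing column(s): ", paste(missing, collapse = ", "))
  }
  raw$participant_id <- as.character(raw$participant_id)
  raw$product_id <- as.character(raw$product_id)
  validate_trials(raw)
  trials <- raw[, setdiff(names(raw), setdiff(.REVIEW_COLS, "product_id"))]
  reviews <- unique(raw[, .REVIEW_COLS])
  dup <- duplicated(reviews$product_id)
  if (any(dup)) {
    stop("read_trials: inconsistent review summaries for product(s): ",
         paste(unique(reviews$product_id[dup]), collapse = ", "))
  }
  rownames(trials) <- NULL
  rownames(reviews) <- NULL
  list(trials = trials, reviews = reviews)
}

validate_trials <- function(raw) {
  errors <- character(0)
  for (col in c("r1_raw", "c1_raw", "r2_raw", "c2_raw")) {
    bad <- !is.finite(raw[[col]]) | raw[[col]] < 0 | raw[[col]] > 500
    if (any(bad)) {
      errors <- c(errors, sprintf("%s outside [0, 500] on %d row(s)",
                                  col, sum(bad)))
    }
  }
  hist_mat <- as.matrix(raw[, paste0("hist_", 1:5)])
  hist_sum <- rowSums(hist_mat)
  bad_n <- hist_sum != raw$n_reviews
  if (any(bad_n)) {
    errors <- c(errors, paste0(
      "histogram does not sum to n_reviews for product(s): ",
      paste(unique(raw$product_id[bad_n]), collapse = ", ")))
  }
  hist_mean <- as.vector(hist_mat %*% (1:5)) / pmax(hist_sum, 1)
  bad_m <- abs(hist_mean - raw$mean_stars) > 0.05 & hist_sum > 0
  if (any(bad_m)) {
    errors <- c(errors, paste0(
      "mean_stars disagrees with histogram (> 0.05) for product(s): ",
      paste(unique(raw$product_id[bad_m]), collapse = ", ")))
  }
  if (length(errors)) {
    stop("read_trials: validation failed:\n  ",
         paste(errors, collapse = "\n  "))
  }
  invisible(TRUE)
}

#' Write a trials file
#'
#' Inverse of [read_trials()]: joins the review summaries back onto the trial
#' rows and writes a single CSV in the canonical schema. Any derived columns
#' present on `trials` (standardized ratings, `m_std`, split flags) are
#' appended after the canonical columns.
#'
#' @param trials Trial data frame (from [read_trials()] or
#'   [simulate_cohort()]).
#' @param reviews Review-summary data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, reviews, path) {
  merged <- merge(trials, reviews, by = "product_id", sort = FALSE)
  lead <- c(.TRIAL_COLS, setdiff(.REVIEW_COLS, "product_id"))
  merged <- merged[, c(lead, setdiff(names(merged), lead))]
  merged <- merged[order(merged$participant_id, merged$product_id), ]
  utils::write.csv(merged, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Z-score ratings within participant
#'
#' Standardizes each of the four judgment columns (first/second liking rating,
#' first/second confidence) separately for each participant, to correct for
#' idiosyncratic use of the slider scale: within a participant each
#' standardized column has mean 0 and unit sample variance (n - 1
#' denominator). The standardized values are written to `r1`, `c1`, `r2`,
#' `c2`.
#'
#' @param trials Trial data frame with the raw judgment columns.
#' @return `trials` with standardized columns filled in.
#' @export
standardize_trials <- function(trials) {
  for (p in unique(trials$participant_id)) {
    idx <- trials$participant_id == p
    for (j in names(.JUDGMENT_COLS)) {
      x <- trials[[.JUDGMENT_COLS[[j]]]][idx]
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) {
        stop("standardize_trials: degenerate (constant) column ",
             .JUDGMENT_COLS[[j]], " for participant ", p)
      }
      trials[[j]][idx] <- (x - mean(x)) / s
    }
  }
  trials
}

#' Median-split flags for confidence and review count
#'
#' `split_confidence()` sets `high_conf = 1` on trials whose raw initial
#' confidence strictly exceeds that participant's median initial confidence
#' (ties and below get 0); the split is computed per participant because
#' confidence scale use is participant-specific. `split_reviews()` flags
#' products whose reviewer count strictly exceeds the median count over the
#' stimulus set; the split is global because the review count is a stimulus
#' property. Both flags are invariant to strictly monotone rescaling of the
#' split variable.
#'
#' @param trials Trial data frame with `c1_raw`.
#' @return `split_confidence`: `trials` with a `high_conf` column.
#' @export
split_confidence <- function(trials) {
  flags <- integer(nrow(trials))
  for (p in unique(trials$participant_id)) {
    idx <- trials$participant_id == p
    med <- stats::median(trials$c1_raw[idx])
    flags[idx] <- as.integer(trials$c1_raw[idx] > med)
  }
  trials$high_conf <- flags
  trials
}

#' @rdname split_confidence
#' @param reviews Review-summary data frame with `n_reviews`.
#' @return `split_reviews`: `reviews` with a `many_reviews` column.
#' @export
split_reviews <- function(reviews) {
  med <- stats::median(reviews$n_reviews)
  reviews$many_reviews <- as.integer(reviews$n_reviews > med)
  reviews
}

#' Map review means onto each participant's standardized rating scale
#'
#' The review mean is shown in star units (1-5) while the model works on each
#' participant's z-scored rating scale. The stars are mapped linearly onto the
#' raw slider range (1 star -> 0, 5 stars -> 500) and then passed through the
#' participant's own first-rating z-transform, so the same product generally
#' lands at different standardized positions for different participants. The
#' map is monotone and affine.
#'
#' @param trials Trial data frame (raw ratings present).
#' @param reviews Review-summary data frame.
#' @return `trials` with an `m_std` column.
#' @export
align_review_means <- function(trials, reviews) {
  m_raw <- (reviews$mean_stars - 1) / 4 * 500
  names(m_raw) <- as.character(reviews$product_id)
  trials$m_std <- NA_real_
  for (p in unique(trials$participant_id)) {
    idx <- trials$participant_id == p
    mu <- mean(trials$r1_raw[idx])
    s <- stats::sd(trials$r1_raw[idx])
    if (!is.finite(s) || s == 0) {
      stop("align_review_means: degenerate r1_raw scale for participant ", p)
    }
    trials$m_std[idx] <- (m_raw[as.character(trials$product_id[idx])] - mu) / s
  }
  trials
}

#' Full preprocessing step
#'
#' Standardizes the four judgment columns, computes both median-split flags,
#' and aligns the review means to each participant's standardized rating
#' scale. This is the table every downstream stage (model fitting, derived
#' measures, regressions) consumes.
#'
#' @param trials,reviews As returned by [read_trials()] or
#'   [simulate_cohort()].
#' @return Trial data frame with columns `r1`, `c1`, `r2`, `c2`, `m_std`,
#'   `high_conf`, `many_reviews` appended.
#' @export
prepare_trials <- function(trials, reviews) {
  trials <- standardize_trials(trials)
  trials <- split_confidence(trials)
  trials <- align_review_means(trials, reviews)
  reviews <- split_reviews(reviews)
  flag <- reviews$many_reviews
  names(flag) <- as.character(reviews$product_id)
  trials$many_reviews <- unname(flag[as.character(trials$product_id)])
  if (any(is.na(trials$many_reviews))) {
    stop("prepare_trials: trials reference products absent from reviews")
  }
  trials
}
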
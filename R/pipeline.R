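# Pipeline orchestration: config handling plus the simulate / fit / analyze
# stages as plain functions. A thin command-line front end over these lives
# in inst/cli/belief-pipeline.R.

.default_config <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    trials_file = NULL,   # defaults to <out_dir>/trials.csv
    cohort = list(),      # overrides passed to cohort_spec()
    fit = list(n_restarts = 10),
    analyze = list(alpha = 0.01),
    verbose = TRUE
  )
}

#' Read a pipeline configuration
#'
#' Reads a YAML configuration file and merges it over the built-in defaults
#' (seed, output directory, cohort-spec overrides, fit settings, regression
#' alpha). With `path = NULL` the defaults are returned.
#'
#' @param path Path to a YAML file, or `NULL`.
#' @param overrides Named list merged over the file values (used by the
#'   command line for `--seed`/`--out`).
#' @return A config list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  config <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("read_config: file not found: ", path)
    config <- utils::modifyList(config, yaml::read_yaml(path))
  }
  config <- utils::modifyList(config, overrides)
  config$seed <- as.integer(config$seed)
  config
}

.log <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

.trials_path <- function(config) {
  config$trials_file %||% file.path(config$out_dir, "trials.csv")
}

#' Pipeline stage: simulate
#'
#' Builds a [cohort_spec()] from the config (config seed + any overrides
#' under `cohort:`), simulates the cohort, and writes `trials.csv`,
#' `reviews.csv` and `true_params.csv` into the output directory. The config
#' used is logged alongside as `config_used.yaml`.
#'
#' @param config List from [read_config()].
#' @return Invisibly, the paths written.
#' @export
run_simulate <- function(config = read_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- do.call(cohort_spec, utils::modifyList(config$cohort,
                                                 list(seed = config$seed)))
  .log(config, "simulate: seed %d, %d participants x %d products",
       config$seed, spec$n_participants, spec$n_products)
  sim <- simulate_cohort(spec)
  paths <- c(
    trials = .trials_path(config),
    reviews = file.path(config$out_dir, "reviews.csv"),
    true_params = file.path(config$out_dir, "true_params.csv")
  )
  write_trials(sim$trials, sim$reviews, paths[["trials"]])
  utils::write.csv(sim$reviews, paths[["reviews"]], row.names = FALSE)
  utils::write.csv(sim$true_params, paths[["true_params"]],
                   row.names = FALSE)
  yaml::write_yaml(config, file.path(config$out_dir, "config_used.yaml"))
  .log(config, "simulate: wrote %s", paste(paths, collapse = ", "))
  invisible(paths)
}

#' Pipeline stage: fit
#'
#' Reads the trials file, preprocesses it, fits the belief-updating model to
#' every participant, and writes the fitted-parameter table
#' (`fitted_params.csv`) and the per-trial derived measures (`derived.csv`:
#' prior, posterior, KL divergence, resistance).
#'
#' @param config List from [read_config()]. Fitting uses
#'   `config$seed + 1000` so the fit restarts are decoupled from the
#'   simulation stream.
#' @return Invisibly, the [fit_belief_model()] object.
#' @export
run_fit <- function(config = read_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- read_trials(.trials_path(config))
  prep <- prepare_trials(dat$trials, dat$reviews)
  .log(config, "fit: %d participants, %d trials, %d restarts",
       length(unique(prep$participant_id)), nrow(prep),
       config$fit$n_restarts)
  fit <- fit_belief_model(prep, n_restarts = config$fit$n_restarts,
                          seed = config$seed + 1000L)
  utils::write.csv(fit$params,
                   file.path(config$out_dir, "fitted_params.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$derived, file.path(config$out_dir, "derived.csv"),
                   row.names = FALSE)
  if (any(!fit$params$converged)) {
    .log(config, "fit: %d participant(s) did not converge",
         sum(!fit$params$converged))
  }
  .log(config,
       "fit: mean cor(prior,R1) = %.3f, cor(post,R2) = %.3f, resistance = %.3f",
       mean(fit$params$corr_prior_r1), mean(fit$params$corr_post_r2),
       mean(fit$params$mean_resistance))
  invisible(fit)
}

#' Pipeline stage: analyze
#'
#' Reads and preprocesses the trials file, runs the behavioral regression
#' battery, writes coefficient and likelihood-ratio tables, a text report,
#' and the coefficient figure, and checks the five qualitative signatures of
#' reliability-weighted integration.
#'
#' @param config List from [read_config()].
#' @return Invisibly, list with `signatures` (named logical vector),
#'   `update`, `confidence`.
#' @export
run_analyze <- function(config = read_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- read_trials(.trials_path(config))
  prep <- prepare_trials(dat$trials, dat$reviews)
  design <- build_design(prep)
  .log(config, "analyze: %d observations, %d participants", nrow(design),
       length(unique(design$participant_id)))
  upd <- fit_update_model(design)
  conf <- fit_confidence_models(design)
  sig <- signature_check(upd, conf, alpha = config$analyze$alpha)

  coefs <- rbind(
    cbind(model = upd$formula_label, upd$coefficients),
    cbind(model = conf$conf_update$formula_label,
          conf$conf_update$coefficients),
    cbind(model = conf$c2_quadratic$formula_label,
          conf$c2_quadratic$coefficients))
  lrts <- rbind(
    cbind(model = upd$formula_label, upd$lrt),
    cbind(model = conf$conf_update$formula_label, conf$conf_update$lrt),
    cbind(model = conf$c2_quadratic$formula_label, conf$c2_quadratic$lrt))
  utils::write.csv(coefs, file.path(config$out_dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(lrts, file.path(config$out_dir, "lrt.csv"),
                   row.names = FALSE)

  grDevices::pdf(file.path(config$out_dir, "coefficients.pdf"),
                 width = 9, height = 4)
  plot_coefficients(upd, conf)
  grDevices::dev.off()

  report <- file.path(config$out_dir, "report.txt")
  sink(report)
  print(upd); cat("\n"); print(conf$conf_update); cat("\n")
  print(conf$c2_quadratic); cat("\nSignature check:\n"); print(sig)
  sink()
  .log(config, "analyze: %d/%d signatures in the expected direction",
       sum(sig), length(sig))
  invisible(list(signatures = sig, update = upd, confidence = conf))
}
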
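# Internal helpers: seed hygiene and truncated-normal draws.

# Set the RNG seed for the duration of the calling function, restoring the
# caller-visible RNG state on exit (same contract as simulate.lm).
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialise RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  restore <- substitute(assign(".Random.seed", s, envir = globalenv()),
                        list(s = old))
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  # keep derived seeds inside 32-bit integer range
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}

# Inverse-CDF sampler for a normal truncated to [a, b].
rtruncnorm <- function(n, mean, sd, a, b) {
  lo <- stats::pnorm(a, mean, sd)
  hi <- stats::pnorm(b, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

truncnorm_mean <- function(mean, sd, a, b) {
  alpha <- (a - mean) / sd
  beta <- (b - mean) / sd
  z <- stats::pnorm(beta) - stats::pnorm(alpha)
  mean + sd * (stats::dnorm(alpha) - stats::dnorm(beta)) / z
}

`%||%` <- function(x, y) if (is.null(x)) y else x
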
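# Internal helpers shared across modules.

# The ten CYP isoforms assayed, in conventional order.
cyp_isoforms <- function() {
  c("1A2", "2A6", "2B6", "2C8", "2C9", "2C19", "2D6", "2E1", "3A4/5")
}

# The four CYPs whose activities are measured directly, and the five whose
# V_max / CL_int are predicted from them.
measured_cyps <- function() c("1A2", "2B6", "2C9", "2C19")
predicted_cyps <- function() c("2A6", "2C8", "2D6", "2E1", "3A4/5")

kinetic_parameters <- function() c("vmax", "km", "clint")

assert_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and strictly positive.", what),
          class = "cypivive_domain_error")
  }
  invisible(x)
}

assert_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", what),
          class = "cypivive_input_error")
  }
  invisible(x)
}

# Run `expr` with a local RNG state seeded by `seed`; the caller's RNG
# state is untouched. `seed = NULL` uses (and advances) the global stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

# Parameters of a lognormal whose *truncated-to-[min, max]* median equals
# `median`. sdlog comes from a 99% central-span heuristic on the range;
# meanlog is root-found (the naive log(median) misses badly when the median
# sits asymmetrically in the range).
calibrate_lognormal <- function(median, min, max) {
  stopifnot(min > 0, min < median, median < max)
  sdlog <- (log(max) - log(min)) / (2 * qnorm(0.995))
  trunc_median <- function(meanlog) {
    a <- stats::pnorm((log(min) - meanlog) / sdlog)
    b <- stats::pnorm((log(max) - meanlog) / sdlog)
    exp(meanlog + sdlog * qnorm((a + b) / 2))
  }
  f <- function(m) trunc_median(m) - median
  root <- stats::uniroot(f, lower = log(min) - 2 * sdlog,
                         upper = log(max) + 2 * sdlog, tol = 1e-10)
  list(meanlog = root$root, sdlog = sdlog)
}

# Rejection-sample `n` draws from lognormal(meanlog, sdlog) truncated to
# [min, max].
rlnorm_trunc <- function(n, meanlog, sdlog, min, max) {
  out <- numeric(n)
  need <- seq_len(n)
  guard <- 0L
  while (length(need) > 0L) {
    guard <- guard + 1L
    if (guard > 1000L) {
      abort("Truncated lognormal sampler failed to converge; calibration infeasible.",
            class = "cypivive_config_error")
    }
    draw <- rlnorm(length(need), meanlog, sdlog)
    ok <- draw >= min & draw <= max
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

rnorm_trunc <- function(n, mean, sd, min, max) {
  out <- numeric(n)
  need <- seq_len(n)
  guard <- 0L
  while (length(need) > 0L) {
    guard <- guard + 1L
    if (guard > 10000L) {
      abort("Truncated normal sampler failed to converge; calibration infeasible.",
            class = "cypivive_config_error")
    }
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= min & draw <= max
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}
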
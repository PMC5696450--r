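#' Fit a Michaelis-Menten curve to one microsomal incubation series
#'
#' Estimates the maximal velocity (`V_max`) and Michaelis constant (`K_m`) of
#' a single enzyme-substrate pair by unweighted nonlinear least squares on the
#' hyperbolic model `v = V_max * S / (K_m + S)`, and derives the intrinsic
#' clearance `CL_int = V_max / K_m`.
#'
#' The optimiser is bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) with `V_max` restricted to `(0, 10 * max(v)]` and
#' `K_m` to `(0, 10 * max(S)]`, started from `V_max = max(v)` and `K_m` at the
#' substrate concentration nearest half-maximal observed velocity. Replicate
#' velocities at identical substrate concentrations are averaged before
#' fitting.
#'
#' @param conc Substrate concentrations, uM. At least four distinct positive
#'   values are required.
#' @param velocity Reaction velocities, pmol/min/mg microsomal protein; same
#'   length as `conc`, all non-negative, not all zero.
#'
#' @return An object of class `mm_fit`: a list with elements `vmax` (pmol/min/mg),
#'   `km` (uM), `clint` (ul/min/mg), `fit_sse` (residual sum of squares),
#'   `converged` (FALSE when the optimiser failed or an estimate sits on a
#'   bound), and `data` (the averaged fitting data). Use [tidy()] / [glance()]
#'   for tibble summaries and [autoplot()] to inspect the fit.
#'
#' @examples
#' s <- c(2.5, 5, 10, 20, 40, 80)
#' fit <- mm_fit(s, 100 * s / (10 + s))
#' glance(fit)
#' @export
mm_fit <- function(conc, velocity) {
  if (!is.numeric(conc) || !is.numeric(velocity) ||
      length(conc) != length(velocity)) {
    abort("`conc` and `velocity` must be numeric vectors of equal length.",
          class = "cypivive_input_error")
  }
  keep <- is.finite(conc) & is.finite(velocity)
  conc <- conc[keep]
  velocity <- velocity[keep]
  if (any(conc <= 0)) {
    abort("All substrate concentrations must be strictly positive.",
          class = "cypivive_domain_error")
  }
  if (any(velocity < 0)) {
    abort("Velocities must be non-negative.", class = "cypivive_domain_error")
  }
  # average replicate incubations at identical S
  if (anyDuplicated(conc)) {
    agg <- tapply(velocity, conc, mean)
    conc <- as.numeric(names(agg))
    velocity <- as.numeric(agg)
  }
  ord <- order(conc)
  conc <- conc[ord]
  velocity <- velocity[ord]
  if (length(conc) < 4L) {
    abort("At least 4 distinct substrate concentrations are required.",
          class = "cypivive_input_error")
  }
  if (all(velocity == 0)) {
    abort("All velocities are zero; kinetics are unidentifiable.",
          class = "cypivive_degenerate_error")
  }

  vmax_hi <- 10 * max(velocity)
  km_hi <- 10 * max(conc)
  half_v <- max(velocity) / 2
  km0 <- conc[which.min(abs(velocity - half_v))]
  start <- list(vmax = max(velocity), km = max(km0, min(conc) / 10))

  dat <- data.frame(s = conc, v = velocity)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vmax * s / (km + s),
      data = dat, start = start,
      lower = c(vmax = 1e-12, km = 1e-12),
      upper = c(vmax = vmax_hi, km = km_hi),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    # profile fallback for surfaces the LM step cannot handle (e.g. flat,
    # fully saturated series): vmax has a closed-form conditional optimum
    # given km, so profile the SSE over a log-spaced km grid and refine
    prof <- mm_profile_fit(conc, velocity, vmax_hi, km_hi)
    est <- c(vmax = prof$vmax, km = prof$km)
    sse <- prof$sse
    converged <- FALSE
  } else {
    est <- coef(fit)
    sse <- sum(stats::resid(fit)^2)
    # flag estimates pinned to a box bound as non-converged
    at_bound <- est[["vmax"]] >= vmax_hi * (1 - 1e-6) ||
      est[["km"]] >= km_hi * (1 - 1e-6) ||
      est[["km"]] <= min(conc) * 1e-6 ||
      est[["vmax"]] <= 1e-9
    converged <- isTRUE(fit$convInfo$isConv) && !at_bound
  }

  structure(
    list(
      vmax = unname(est[["vmax"]]),
      km = unname(est[["km"]]),
      clint = compute_clint(unname(est[["vmax"]]), unname(est[["km"]])),
      fit_sse = sse,
      converged = converged,
      data = tibble::tibble(substrate_conc_uM = conc,
                            velocity_pmol_min_mg = velocity)
    ),
    class = "mm_fit"
  )
}

# Conditional-on-km least squares: v = vmax * g(km) with g = s/(km+s) is
# linear in vmax, so vmax*(km) = sum(v*g)/sum(g^2). Profile over km.
mm_profile_fit <- function(conc, velocity, vmax_hi, km_hi) {
  sse_at <- function(km) {
    g <- conc / (km + conc)
    vmax <- min(max(sum(velocity * g) / sum(g^2), 1e-12), vmax_hi)
    c(vmax = vmax, sse = sum((velocity - vmax * g)^2))
  }
  km_grid <- exp(seq(log(min(conc) * 1e-4), log(km_hi), length.out = 400))
  sses <- vapply(km_grid, function(k) sse_at(k)[["sse"]], numeric(1))
  i <- which.min(sses)
  lo <- km_grid[max(i - 1L, 1L)]
  hi <- km_grid[min(i + 1L, length(km_grid))]
  opt <- stats::optimize(function(k) sse_at(k)[["sse"]], c(lo, hi))
  km <- if (opt$objective < sses[i]) opt$minimum else km_grid[i]
  best <- sse_at(km)
  list(vmax = unname(best[["vmax"]]), km = km, sse = unname(best[["sse"]]))
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit\n")
  cat(sprintf("  V_max  %.4g pmol/min/mg\n", x$vmax))
  cat(sprintf("  K_m    %.4g uM\n", x$km))
  cat(sprintf("  CL_int %.4g ul/min/mg\n", x$clint))
  cat(sprintf("  SSE %.4g | converged: %s\n", x$fit_sse, x$converged))
  invisible(x)
}

#' Intrinsic clearance from Michaelis-Menten parameters
#'
#' `CL_int = V_max / K_m`; with `V_max` in pmol/min/mg protein and `K_m` in
#' uM (= pmol/ul), the ratio is in ul/min/mg protein.
#'
#' @param vmax Maximal velocity, pmol/min/mg protein (>= 0). Vectorised.
#' @param km Michaelis constant, uM (> 0). Vectorised.
#' @return Intrinsic clearance, ul/min/mg protein.
#' @examples
#' compute_clint(100, 10)
#' @export
compute_clint <- function(vmax, km) {
  if (any(!is.finite(km)) || any(km <= 0)) {
    abort("`km` must be strictly positive.", class = "cypivive_domain_error")
  }
  if (any(!is.finite(vmax)) || any(vmax < 0)) {
    abort("`vmax` must be non-negative.", class = "cypivive_domain_error")
  }
  vmax / km
}

#' Fit Michaelis-Menten kinetics for every subject and CYP in a velocity table
#'
#' Takes long-format incubation data (one row per substrate concentration) and
#' fits [mm_fit()] per `subject_id` x `cyp` group.
#'
#' @param data A data frame with columns `subject_id`, `cyp`,
#'   `substrate_conc_uM`, `velocity_pmol_min_mg`.
#' @return A tibble with one row per subject-CYP pair: `subject_id`, `cyp`,
#'   `vmax`, `km`, `clint`, `fit_sse`, `converged`.
#' @examples
#' curves <- generate_kinetic_curves(vmax = 100, km = 10, cyp = "2C9",
#'                                   noise_cv = 0, seed = 1)
#' curves$subject_id <- "S1"
#' fit_kinetics(curves)
#' @export
fit_kinetics <- function(data) {
  required <- c("subject_id", "cyp", "substrate_conc_uM", "velocity_pmol_min_mg")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "cypivive_input_error")
  }
  data %>%
    dplyr::group_by(.data$subject_id, .data$cyp) %>%
    dplyr::group_modify(function(df, key) {
      f <- mm_fit(df$substrate_conc_uM, df$velocity_pmol_min_mg)
      tibble::tibble(vmax = f$vmax, km = f$km, clint = f$clint,
                     fit_sse = f$fit_sse, converged = f$converged)
    }) %>%
    dplyr::ungroup()
}

#' @rdname mm_fit
#' @param x,object An `mm_fit` object.
#' @param ... Unused.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("vmax", "km"),
    estimate = c(x$vmax, x$km),
    unit = c("pmol/min/mg", "uM")
  )
}

#' @rdname mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(vmax = x$vmax, km = x$km, clint = x$clint,
                 fit_sse = x$fit_sse, converged = x$converged,
                 n_points = nrow(x$data))
}
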
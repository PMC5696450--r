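# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, explicit normal-equation algebra and
# full enumeration, so they can arbitrate the optimised implementations.

# Grid search over the (V_max, K_m) lattice minimising SSE.
oracle_mm_grid <- function(s, v, vmax_range, km_range, n_grid = 120) {
  vg <- seq(vmax_range[1], vmax_range[2], length.out = n_grid)
  kg <- exp(seq(log(km_range[1]), log(km_range[2]), length.out = n_grid))
  best <- c(vmax = NA_real_, km = NA_real_, sse = Inf)
  for (vm in vg) {
    for (km in kg) {
      sse <- sum((v - vm * s / (km + s))^2)
      if (sse < best[["sse"]]) best <- c(vmax = vm, km = km, sse = sse)
    }
  }
  as.list(best)
}

# SPSS-style stepwise selection re-implemented from scratch with explicit
# RSS algebra (normal equations), independent of lm/add1/drop1.
oracle_stepwise <- function(y, X, p_enter = 0.05, p_remove = 0.10) {
  n <- length(y)
  rss_of <- function(preds) {
    Xm <- cbind(1, as.matrix(X[, preds, drop = FALSE]))
    beta <- solve(crossprod(Xm), crossprod(Xm, y))
    sum((y - Xm %*% beta)^2)
  }
  partial_p <- function(preds, term) {
    full <- rss_of(preds)
    red <- rss_of(setdiff(preds, term))
    df2 <- n - length(preds) - 1
    f <- (red - full) / (full / df2)
    stats::pf(f, 1, df2, lower.tail = FALSE)
  }
  current <- character()
  repeat {
    changed <- FALSE
    pool <- setdiff(colnames(X), current)
    if (length(pool) > 0) {
      ps <- vapply(pool, function(cand) partial_p(c(current, cand), cand),
                   numeric(1))
      if (min(ps) <= p_enter) {
        current <- c(current, pool[which.min(ps)])
        changed <- TRUE
      }
    }
    repeat {
      if (length(current) == 0) break
      ps <- vapply(current, function(term) partial_p(current, term),
                   numeric(1))
      if (max(ps) >= p_remove) {
        current <- setdiff(current, current[which.max(ps)])
        changed <- TRUE
      } else {
        break
      }
    }
    if (!changed) break
  }
  sort(current)
}

# Exhaustive minimum cover over all subsets of the predictor universe.
# `pred_sets` is a list (one per response) of lists of character vectors
# (one per candidate model). Returns the minimum covering size.
oracle_min_cover_size <- function(pred_sets) {
  universe <- sort(unique(unlist(pred_sets)))
  p <- length(universe)
  best <- Inf
  for (mask in 0:(2^p - 1)) {
    s <- universe[bitwAnd(mask, 2^(seq_len(p) - 1)) > 0]
    ok <- all(vapply(pred_sets, function(cands) {
      any(vapply(cands, function(req) all(req %in% s), logical(1)))
    }, logical(1)))
    if (ok) best <- min(best, length(s))
  }
  best
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_ranksum_exact <- function(a, b) {
  n <- length(a)
  r <- rank(c(a, b))
  mu <- n * length(b) / 2
  obs_u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + length(b), n)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mean(abs(us - mu) >= abs(obs_u - mu) - 1e-9)
}

# Normal-approximation Mann-Whitney with tie correction, no continuity
# correction, from the closed form.
oracle_ranksum_normal <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  tie_adj <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_adj)
  z <- (u - n1 * n2 / 2) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

# Pearson chi-square on a 2x2 table from the definition.
oracle_chi2 <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Activity table of a single synthetic subject holding the published
# measured medians for the four driver CYPs (vmax and clint).
median_donor_activities <- function() {
  published_activity_summary() |>
    dplyr::filter(cyp %in% c("1A2", "2B6", "2C9", "2C19"),
                  parameter %in% c("vmax", "clint")) |>
    dplyr::transmute(subject_id = "median-donor", cyp, parameter,
                     value = median)
}
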
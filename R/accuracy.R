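#' Average fold-error (AFE) of a predicted clearance
#'
#' `AFE = 10^((1/N) * sum(log10(predicted / observed_r)))` over the `N`
#' literature report means; algebraically the predicted value divided by the
#' geometric mean of the observed report means. A single pooled observed mean
#' (`N = 1`) reduces to a simple ratio.
#'
#' @param predicted Predicted mean clearance, ml/min (> 0).
#' @param observed Vector of observed report means, ml/min (all > 0).
#' @return Dimensionless fold-error (> 0); 1 is perfect agreement.
#' @examples
#' afe(2, c(1, 4))
#' @export
afe <- function(predicted, observed) {
  assert_scalar_number(predicted, "predicted")
  assert_positive(predicted, "predicted")
  if (length(observed) < 1) {
    abort("Need at least one observed report mean.",
          class = "cypivive_input_error")
  }
  assert_positive(observed, "observed")
  10^mean(log10(predicted / observed))
}

#' Individual fold-error (IFE) of per-subject predictions
#'
#' Per-subject analogue of [afe()]: each predicted individual clearance
#' divided by the geometric mean of the observed report means.
#'
#' @param predicted Vector of predicted individual clearances, ml/min (> 0).
#' @param observed Vector of observed report means, ml/min (all > 0).
#' @return Vector of dimensionless fold-errors, one per subject.
#' @examples
#' ife(c(2, 8), c(2, 8))
#' @export
ife <- function(predicted, observed) {
  assert_positive(predicted, "predicted")
  assert_positive(observed, "observed")
  geo <- 10^mean(log10(observed))
  predicted / geo
}

#' Fraction of fold-errors inside the 2-fold window
#'
#' Counts ratios `r` with `0.5 <= r <= 2` (closed interval). The window is
#' symmetric on the log scale, so it is invariant under `r -> 1/r`.
#'
#' @param ratios Vector of positive fold-errors or prediction ratios.
#' @return A tibble with `n`, `count` and `fraction`.
#' @examples
#' two_fold_fraction(c(0.4, 0.5, 1, 2, 3))
#' @export
two_fold_fraction <- function(ratios) {
  if (length(ratios) == 0) {
    abort("Cannot compute a fraction from an empty vector.",
          class = "cypivive_input_error")
  }
  assert_positive(ratios, "ratios")
  count <- sum(ratios >= 0.5 & ratios <= 2)
  tibble::tibble(n = length(ratios), count = count,
                 fraction = count / length(ratios))
}

#' Individual prediction-to-measurement ratio summary
#'
#' Element-wise ratios of predicted to measured values with their median,
#' range and 2-fold concordance — the per-case accuracy summary used for
#' predicted versus measured `CL_int`.
#'
#' @param predicted,measured Equal-length positive vectors.
#' @return A tibble with `n`, `ratio_median`, `ratio_min`, `ratio_max`,
#'   `within_two_fold` (count) and `fraction`.
#' @examples
#' ratio_accuracy(c(1, 2, 9), c(1, 1, 3))
#' @export
ratio_accuracy <- function(predicted, measured) {
  if (length(predicted) != length(measured)) {
    abort("`predicted` and `measured` must have equal length.",
          class = "cypivive_input_error")
  }
  assert_positive(measured, "measured")
  assert_positive(predicted, "predicted")
  r <- predicted / measured
  tf <- two_fold_fraction(r)
  tibble::tibble(n = tf$n, ratio_median = median(r), ratio_min = min(r),
                 ratio_max = max(r), within_two_fold = tf$count,
                 fraction = tf$fraction)
}

#' Fold-range (max/min) of a positive quantity
#'
#' Summarises inter-individual variation as the ratio of the largest to the
#' smallest value.
#'
#' @param values Positive vector, or length-2 `c(min, max)` range.
#' @return Dimensionless fold-change (>= 1).
#' @examples
#' fold_range(c(235.9, 958.3))
#' @export
fold_range <- function(values) {
  assert_positive(values, "values")
  max(values) / min(values)
}

#' Two-sided Mann-Whitney U comparison
#'
#' Rank-sum comparison of two samples, as used to compare measured versus
#' predicted distributions. Exact enumeration is used for small untied
#' samples (`min(n) <= 8`); otherwise the normal approximation with tie
#' correction (no continuity correction, matching the closed form).
#'
#' @param a,b Numeric samples (non-empty).
#' @return Two-sided p-value.
#' @examples
#' rank_sum_compare(c(1, 2, 3), c(10, 11, 12))
#' @export
rank_sum_compare <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    abort("Both samples must be non-empty.", class = "cypivive_input_error")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- min(length(a), length(b)) <= 8 && !ties
  suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = FALSE)$p.value
  )
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' Compares within-2-fold concordance counts between two prediction sources.
#' No continuity correction by default (SPSS "Pearson Chi-Square" row);
#' enable Yates correction with `correct = TRUE`.
#'
#' @param table2x2 A 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A tibble with `statistic` (1 df chi-square) and `p_value`.
#' @examples
#' chi2_independence(matrix(c(93, 12, 103, 2), nrow = 2, byrow = TRUE))
#' @export
chi2_independence <- function(table2x2, correct = FALSE) {
  m <- as.matrix(table2x2)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m))) {
    abort("`table2x2` must be a 2x2 matrix of non-negative integer counts.",
          class = "cypivive_input_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Degenerate table: a margin is zero.",
          class = "cypivive_degenerate_error")
  }
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  tibble::tibble(statistic = unname(ct$statistic),
                 p_value = unname(ct$p.value))
}

#' Normality screen: Kolmogorov-Smirnov (Lilliefors) and Shapiro-Wilk
#'
#' Runs both tests on one sample. Downstream comparisons switch to rank-based
#' methods when either test rejects at 0.05; in the microsome data most
#' activity distributions are right-skewed and fail both. A constant sample
#' is reported with the `p = 0` convention (degenerate, treated as
#' non-normal).
#'
#' @param values Numeric sample, `n >= 3`.
#' @return A tibble with columns `test`, `statistic`, `p_value`.
#' @examples
#' normality_check(rlnorm(50))
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    abort("Need at least 3 finite values.", class = "cypivive_input_error")
  }
  if (stats::sd(values) == 0) {
    return(tibble::tibble(
      test = c("kolmogorov_smirnov", "shapiro_wilk"),
      statistic = NA_real_, p_value = 0
    ))
  }
  ks <- nortest::lillie.test(values)
  sw <- shapiro.test(values)
  tibble::tibble(
    test = c("kolmogorov_smirnov", "shapiro_wilk"),
    statistic = c(unname(ks$statistic), unname(sw$statistic)),
    p_value = c(ks$p.value, sw$p.value)
  )
}

#' Per-drug accuracy report for extrapolated clearances
#'
#' Summarises a set of [extrapolate_cohort()] results against the
#' literature-observed clearances: AFE of the cohort mean, the IFE
#' distribution and its 2-fold concordance, per drug and clearance source.
#'
#' @param results Tibble from [extrapolate_cohort()] (may combine both
#'   `clint_source` values).
#' @param drugs Drug parameter table with observed clearances; defaults to
#'   [published_drugs()].
#' @return A tibble with one row per drug x source: `drug`, `cyp`,
#'   `clint_source`, `n`, `predicted_mean`, `predicted_sd`, `observed_mean`,
#'   `afe`, `ife_median`, `within_two_fold`, `fraction`.
#' @export
evaluate_accuracy <- function(results, drugs = published_drugs()) {
  if (nrow(results) == 0) {
    abort("`results` is empty.", class = "cypivive_input_error")
  }
  results %>%
    dplyr::group_by(.data$drug, .data$cyp, .data$clint_source) %>%
    dplyr::group_modify(function(df, key) {
      obs <- drugs$observed_clh_mean[drugs$drug == key$drug]
      if (length(obs) != 1) {
        abort(sprintf("No observed clearance for drug '%s'.", key$drug),
              class = "cypivive_input_error")
      }
      pos <- df$clh_ml_min[df$clh_ml_min > 0]
      ife_v <- ife(pos, obs)
      tf <- two_fold_fraction(ife_v)
      tibble::tibble(
        n = nrow(df),
        predicted_mean = mean(df$clh_ml_min),
        predicted_sd = sd(df$clh_ml_min),
        observed_mean = obs,
        afe = afe(mean(df$clh_ml_min), obs),
        ife_median = median(ife_v),
        within_two_fold = tf$count,
        fraction = tf$fraction
      )
    }) %>%
    dplyr::ungroup()
}
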
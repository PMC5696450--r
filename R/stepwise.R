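#' Stepwise multiple linear regression with F-to-enter / F-to-remove rules
#'
#' Selects predictors for one CYP's kinetic parameter from the same parameter
#' of other CYPs, using the classic SPSS stepwise convention: at each
#' iteration the not-yet-entered candidate with the smallest partial-F
#' p-value enters if that p-value is `<= p_enter`; then entered terms with
#' partial-F p-value `>= p_remove` are removed one at a time (largest first);
#' the loop runs until neither step changes the model (guarded at
#' `2 * length(candidates)` iterations). An intercept-only model is a legal
#' result.
#'
#' @param data Either a long activity table (columns `subject_id`, `cyp`,
#'   `parameter`, `value`) or a wide data frame with one column per CYP
#'   holding a single kinetic parameter.
#' @param response Response CYP isoform (its column / long-table entries).
#' @param candidates Character vector of candidate predictor CYPs; defaults
#'   to every other CYP column present.
#' @param parameter For long-format `data`, which kinetic parameter to model
#'   (`"vmax"`, `"km"` or `"clint"`).
#' @param p_enter Entry threshold on the partial-F p-value (default 0.05).
#' @param p_remove Removal threshold (default 0.10; must be `> p_enter`).
#' @return A [cyp_model()] with `provenance = "fitted"`, carrying the
#'   underlying `lm` fit and training data (so [prediction_interval()] works).
#' @examples
#' set.seed(1)
#' x <- rlnorm(60, 0, 0.5)
#' d <- tibble::tibble(`2C9` = x, `2B6` = rlnorm(60, 0, 0.5),
#'                     `2C8` = 1.7 + 0.9 * x + rnorm(60, 0, 0.4))
#' stepwise_fit(d, "2C8", c("2C9", "2B6"))
#' @export
stepwise_fit <- function(data, response, candidates = NULL, parameter = NULL,
                         p_enter = 0.05, p_remove = 0.10) {
  if (p_remove <= p_enter) {
    abort("`p_remove` must exceed `p_enter` (otherwise the loop can cycle).",
          class = "cypivive_config_error")
  }
  wide <- as_wide_activity(data, parameter)
  if (!response %in% names(wide)) {
    abort(sprintf("Response CYP '%s' not found in data.", response),
          class = "cypivive_input_error")
  }
  candidates <- candidates %||% setdiff(names(wide), c(response, "subject_id"))
  if (response %in% candidates) {
    abort("`response` must not be among `candidates`.",
          class = "cypivive_input_error")
  }
  missing_cand <- setdiff(candidates, names(wide))
  if (length(missing_cand) > 0) {
    abort(paste0("Candidate CYP(s) absent from data: ",
                 paste(missing_cand, collapse = ", ")),
          class = "cypivive_input_error")
  }

  df <- wide[, c(response, candidates), drop = FALSE]
  complete <- stats::complete.cases(df)
  if (any(!complete)) {
    inform(sprintf("Dropped %d subject(s) with missing values.", sum(!complete)))
    df <- df[complete, , drop = FALSE]
  }
  n <- nrow(df)

  fit_on <- function(preds) {
    fml <- if (length(preds) == 0) {
      stats::reformulate("1", response = sprintf("`%s`", response))
    } else {
      stats::reformulate(sprintf("`%s`", preds),
                         response = sprintf("`%s`", response))
    }
    lm(fml, data = df)
  }
  term_pvalues <- function(fit) {
    # partial F of each term = squared t; identical p-values
    sm <- summary(fit)$coefficients
    rows <- rownames(sm) != "(Intercept)"
    p <- sm[rows, "Pr(>|t|)"]
    names(p) <- gsub("`", "", rownames(sm)[rows])
    p
  }

  current <- character()
  for (iter in seq_len(2L * length(candidates) + 1L)) {
    changed <- FALSE
    # --- entry step
    pool <- setdiff(candidates, current)
    if (length(pool) > 0) {
      if (n <= length(current) + 1 + 2) {
        abort(sprintf("Insufficient data: n = %d with %d term(s) in the model.",
                      n, length(current)),
              class = "cypivive_insufficient_data")
      }
      entry_p <- purrr::map_dbl(pool, function(cand) {
        term_pvalues(fit_on(c(current, cand)))[[cand]]
      })
      best <- which.min(entry_p)
      if (entry_p[best] <= p_enter) {
        current <- c(current, pool[best])
        changed <- TRUE
      }
    }
    # --- removal step
    repeat {
      if (length(current) == 0) break
      p <- term_pvalues(fit_on(current))
      worst <- which.max(p)
      if (p[worst] >= p_remove) {
        current <- setdiff(current, names(p)[worst])
        changed <- TRUE
      } else {
        break
      }
    }
    if (!changed) break
  }

  final <- fit_on(current)
  sm <- summary(final)
  k <- length(current)
  cf <- coef(final)
  terms <- if (k > 0) setNames(unname(cf[-1]), current) else numeric()
  fstat <- if (k > 0) unname(sm$fstatistic[1]) else NA_real_
  pval <- if (k > 0) {
    unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE))
  } else {
    NA_real_
  }
  cyp_model(
    cyp = response, parameter = parameter %||% "value",
    intercept = unname(cf[1]), terms = terms, n = n,
    f_stat = fstat, p_value = pval,
    r2 = if (k > 0) sm$r.squared else 0,
    r2_adj = if (k > 0) sm$adj.r.squared else NA_real_,
    provenance = "fitted", fit = final, training = df
  )
}

# Accepts a long activity table (subject_id, cyp, parameter, value) or an
# already-wide frame; returns wide with one column per CYP.
as_wide_activity <- function(data, parameter = NULL) {
  long_cols <- c("subject_id", "cyp", "parameter", "value")
  if (all(long_cols %in% names(data))) {
    if (is.null(parameter)) {
      pars <- unique(data$parameter)
      if (length(pars) != 1) {
        abort("Long-format data holds several parameters; pass `parameter`.",
              class = "cypivive_input_error")
      }
      parameter <- pars
    }
    data %>%
      dplyr::filter(.data$parameter == !!parameter) %>%
      dplyr::select("subject_id", "cyp", "value") %>%
      tidyr::pivot_wider(names_from = "cyp", values_from = "value")
  } else {
    tibble::as_tibble(data)
  }
}

#' 95% prediction interval of a fitted descriptive model
#'
#' Standard new-observation interval of the underlying linear model at the
#' supplied predictor values. Only available for models fitted in-session
#' ([stepwise_fit()]); registry models published without individual-level
#' training data cannot support it.
#'
#' @param model A [cyp_model()] with `provenance = "fitted"`.
#' @param inputs Named list/vector (or data frame) of predictor CYP values.
#' @param level Coverage level, default 0.95.
#' @return A tibble with columns `fit`, `low`, `high` (one row per input row).
#' @export
prediction_interval <- function(model, inputs, level = 0.95) {
  stopifnot(inherits(model, "cyp_model"))
  if (model$provenance != "fitted" || is.null(model$fit)) {
    abort("Prediction intervals need a fitted model with training data; published registry models do not carry them.",
          class = "cypivive_unsupported")
  }
  newdata <- if (is.data.frame(inputs)) inputs else
    tibble::as_tibble(as.list(inputs))
  pr <- predict(model$fit, newdata = newdata, interval = "prediction",
                level = level)
  tibble::tibble(fit = pr[, "fit"], low = pr[, "lwr"], high = pr[, "upr"])
}
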
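#' Construct a descriptive CYP activity model
#'
#' A descriptive model is a multiple linear regression predicting one CYP's
#' kinetic parameter (`vmax`, `km` or `clint`) from the *same* parameter of
#' other CYPs, e.g. `CL_int(2C8) = 1.693 + 0.862 * CL_int(2C9)`.
#'
#' @param cyp Response CYP isoform (e.g. `"2C8"`).
#' @param parameter Kinetic parameter, one of `"vmax"`, `"km"`, `"clint"`.
#' @param intercept Model intercept, units of the response parameter.
#' @param terms Named numeric vector of coefficients, names = predictor CYPs.
#'   May be empty (intercept-only model).
#' @param n Number of subjects used to fit the model.
#' @param f_stat,p_value,r2,r2_adj Fit statistics; when `r2` is given and the
#'   others are omitted they are completed with [model_stats()].
#' @param provenance `"published"` for registry models shipped with the
#'   package, `"fitted"` for models estimated by [stepwise_fit()].
#' @param fit Optional underlying `lm` object (fitted provenance only).
#' @param training Optional training data frame (fitted provenance only);
#'   required by [prediction_interval()].
#' @return An object of class `cyp_model`.
#' @examples
#' m <- cyp_model("2C8", "clint", 1.693, c("2C9" = 0.862), n = 105, r2 = 0.235)
#' glance(m)
#' @export
cyp_model <- function(cyp, parameter, intercept, terms = numeric(),
                      n = NA_integer_, f_stat = NULL, p_value = NA_real_,
                      r2 = NA_real_, r2_adj = NULL,
                      provenance = c("published", "fitted"),
                      fit = NULL, training = NULL) {
  if (!is.character(parameter) || length(parameter) != 1L) {
    abort("`parameter` must be a single string.",
          class = "cypivive_input_error")
  }
  provenance <- match.arg(provenance)
  assert_scalar_number(intercept, "intercept")
  terms <- unlist(terms)
  if (length(terms) == 0) terms <- setNames(numeric(), character())
  if (length(terms) > 0 && (is.null(names(terms)) || any(names(terms) == ""))) {
    abort("`terms` must be a named numeric vector (names = predictor CYPs).",
          class = "cypivive_input_error")
  }
  k <- length(terms)
  if ((is.null(f_stat) || is.null(r2_adj)) && is.finite(r2) && k >= 1 &&
      is.finite(n) && n > k + 1) {
    ms <- model_stats(r2, n, k)
    f_stat <- f_stat %||% ms$f_stat
    r2_adj <- r2_adj %||% ms$r2_adj
  }
  structure(
    list(cyp = cyp, parameter = parameter, intercept = intercept,
         terms = terms, n = as.integer(n),
         f_stat = f_stat %||% NA_real_, p_value = p_value,
         r2 = r2, r2_adj = r2_adj %||% NA_real_,
         provenance = provenance, fit = fit, training = training),
    class = "cyp_model"
  )
}

#' @export
print.cyp_model <- function(x, ...) {
  rhs <- if (length(x$terms) == 0) {
    ""
  } else {
    paste0(sprintf(" %+.4g x %s", unname(x$terms), names(x$terms)),
           collapse = "")
  }
  cat(sprintf("<cyp_model [%s]> %s(%s) = %.4g%s\n", x$provenance,
              x$parameter, x$cyp, x$intercept, rhs))
  if (is.finite(x$r2)) {
    cat(sprintf("  n = %d, F = %.3f, P = %.3g, R2 = %.3f, R2_adj = %.3f\n",
                x$n, x$f_stat, x$p_value, x$r2, x$r2_adj))
  }
  invisible(x)
}

#' @rdname cyp_model
#' @param x,object A `cyp_model`.
#' @param ... Unused.
#' @export
tidy.cyp_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$terms)),
    estimate = c(x$intercept, unname(x$terms))
  )
}

#' @rdname cyp_model
#' @export
glance.cyp_model <- function(x, ...) {
  tibble::tibble(cyp = x$cyp, parameter = x$parameter, n = x$n,
                 n_predictors = length(x$terms), f_stat = x$f_stat,
                 p_value = x$p_value, r2 = x$r2, r2_adj = x$r2_adj,
                 provenance = x$provenance)
}

#' F statistic and adjusted R-squared of a linear model
#'
#' Recovers the global F statistic and the adjusted coefficient of
#' determination from `R^2`, the sample size `n` and the number of predictors
#' `k`: `F = (R2/k) / ((1 - R2)/(n - k - 1))` and
#' `R2_adj = 1 - (1 - R2)(n - 1)/(n - k - 1)`.
#'
#' @param r2 Coefficient of determination, in `[0, 1]`. `r2 = 1` yields an
#'   infinite F.
#' @param n Number of observations (`n > k + 1`).
#' @param k Number of predictors (`k >= 1`).
#' @return A tibble with columns `f_stat` and `r2_adj`.
#' @examples
#' model_stats(0.235, 105, 1)
#' @export
model_stats <- function(r2, n, k) {
  if (any(r2 < 0 | r2 > 1)) {
    abort("`r2` must lie in [0, 1].", class = "cypivive_domain_error")
  }
  if (any(k < 1) || any(n <= k + 1)) {
    abort("Need k >= 1 and n > k + 1.", class = "cypivive_input_error")
  }
  f <- ifelse(r2 == 1, Inf, (r2 / k) / ((1 - r2) / (n - k - 1)))
  tibble::tibble(f_stat = f, r2_adj = 1 - (1 - r2) * (n - 1) / (n - k - 1))
}

#' Evaluate a descriptive model at given predictor activities
#'
#' Computes `intercept + sum(coef * input)`. Negative predictions are
#' returned as-is (never clamped) with a warning, since silent clamping would
#' distort downstream clearance extrapolation.
#'
#' @param model A [cyp_model()].
#' @param inputs Named list or vector mapping predictor CYP to its activity
#'   value (same kinetic parameter as the model response). Extra entries are
#'   ignored; every model predictor must be present.
#' @param quiet Suppress the negative-prediction warning.
#' @return The predicted activity (scalar, or vector if inputs are vectors).
#' @examples
#' m <- published_models() |> registry_get("2C8", "clint")
#' apply_model(m, c("2C9" = 1.17))
#' @export
apply_model <- function(model, inputs, quiet = FALSE) {
  stopifnot(inherits(model, "cyp_model"))
  inputs <- as.list(inputs)
  need <- names(model$terms)
  missing_preds <- setdiff(need, names(inputs))
  if (length(missing_preds) > 0) {
    abort(paste0("Missing predictor value(s): ",
                 paste(missing_preds, collapse = ", ")),
          class = "cypivive_input_error")
  }
  out <- model$intercept
  for (p in need) out <- out + model$terms[[p]] * inputs[[p]]
  if (!quiet && any(out < 0)) {
    warn(sprintf("Model %s(%s) produced %d negative prediction(s); returned unclamped.",
                 model$parameter, model$cyp, sum(out < 0)),
         class = "cypivive_negative_prediction")
  }
  out
}

new_cyp_registry <- function(models, provenance) {
  keys <- purrr::map_chr(models, ~ paste(.x$cyp, .x$parameter, sep = "/"))
  if (anyDuplicated(keys)) {
    abort("Registry holds more than one model for the same (cyp, parameter).",
          class = "cypivive_config_error")
  }
  out <- tibble::tibble(
    cyp = purrr::map_chr(models, "cyp"),
    parameter = purrr::map_chr(models, "parameter"),
    model = models
  )
  structure(out, class = c("cyp_registry", class(out)),
            provenance = provenance)
}

#' @export
print.cyp_registry <- function(x, ...) {
  cat(sprintf("<cyp_registry: %d models, provenance '%s'>\n",
              nrow(x), attr(x, "provenance")))
  purrr::walk(x$model, print)
  invisible(x)
}

#' Published descriptive-model registry
#'
#' Loads the packaged registry of eleven published descriptive models: five
#' for `V_max`, five for `CL_int` (responses CYP2A6, 2C8, 2D6, 2E1, 3A4/5)
#' and one for `K_m` (CYP3A4/5). All predictors are drawn from the four
#' measured CYPs (1A2, 2B6, 2C9, 2C19). Note the `K_m` model is carried for
#' completeness but [predict_cohort()] derives `K_m` as `V_max / CL_int`
#' instead (see [derive_km()]).
#'
#' @param path Optional path to an alternative registry JSON file.
#' @return A `cyp_registry`: a tibble with columns `cyp`, `parameter` and a
#'   `model` list-column of [cyp_model()] objects.
#' @examples
#' published_models()
#' @export
published_models <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cyp_models_published.json",
                                package = "cypivive", mustWork = TRUE)
  read_model_registry(path)
}

#' Read / write a model registry as structured text (JSON)
#'
#' The on-disk format stores, per model: response `cyp` and `parameter`,
#' `intercept`, `terms` (list of `{cyp, coef}`), `n`, `f_stat`, `p_value`,
#' `r2`, `r2_adj`; plus a top-level `provenance`. Numeric fields round-trip
#' at full double precision.
#'
#' @param path File path.
#' @return `read_model_registry()` returns a `cyp_registry`;
#'   `write_model_registry()` returns `path` invisibly.
#' @examples
#' reg <- published_models()
#' tmp <- tempfile(fileext = ".json")
#' write_model_registry(reg, tmp)
#' identical(nrow(read_model_registry(tmp)), nrow(reg))
#' @export
read_model_registry <- function(path) {
  raw <- jsonlite::read_json(path)
  if (is.null(raw$models)) {
    abort("Registry file has no `models` element.",
          class = "cypivive_input_error")
  }
  models <- purrr::map(raw$models, function(m) {
    coefs <- purrr::map_dbl(m$terms, "coef")
    names(coefs) <- purrr::map_chr(m$terms, "cyp")
    cyp_model(
      cyp = m$cyp, parameter = m$parameter, intercept = m$intercept,
      terms = coefs, n = m$n %||% NA_integer_,
      f_stat = m$f_stat, p_value = m$p_value %||% NA_real_,
      r2 = m$r2 %||% NA_real_, r2_adj = m$r2_adj,
      provenance = raw$provenance %||% "published"
    )
  })
  new_cyp_registry(models, provenance = raw$provenance %||% "published")
}

#' @rdname read_model_registry
#' @param registry A `cyp_registry`.
#' @export
write_model_registry <- function(registry, path) {
  stopifnot(inherits(registry, "cyp_registry"))
  payload <- list(
    provenance = attr(registry, "provenance"),
    models = purrr::map(registry$model, function(m) {
      list(cyp = m$cyp, parameter = m$parameter, intercept = m$intercept,
           terms = purrr::imap(unclass(m$terms),
                               function(v, nm) list(cyp = nm, coef = v)) |>
             unname(),
           n = m$n, f_stat = m$f_stat, p_value = m$p_value,
           r2 = m$r2, r2_adj = m$r2_adj)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Look up one model in a registry
#'
#' @param registry A `cyp_registry`.
#' @param cyp Response CYP isoform.
#' @param parameter Kinetic parameter (`"vmax"`, `"km"`, `"clint"`).
#' @return A [cyp_model()]; errors if absent.
#' @examples
#' registry_get(published_models(), "2C8", "clint")
#' @export
registry_get <- function(registry, cyp, parameter) {
  stopifnot(inherits(registry, "cyp_registry"))
  hit <- which(registry$cyp == cyp & registry$parameter == parameter)
  if (length(hit) != 1L) {
    abort(sprintf("Registry has no model for %s(%s).", parameter, cyp),
          class = "cypivive_config_error")
  }
  registry$model[[hit]]
}
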
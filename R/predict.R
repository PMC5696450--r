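#' Back-calculate the Michaelis constant from V_max and CL_int
#'
#' Since `CL_int = V_max / K_m`, the Michaelis constant of a predicted
#' activity profile is `K_m = V_max / CL_int`. This is how `K_m` is completed
#' for the five predicted CYPs, whose regression models cover `V_max` and
#' `CL_int` only.
#'
#' @param vmax Maximal velocity, pmol/min/mg protein. Vectorised.
#' @param clint Intrinsic clearance, ul/min/mg protein (> 0). Vectorised.
#' @return `K_m` in uM.
#' @examples
#' derive_km(897.7, 507.5)
#' @export
derive_km <- function(vmax, clint) {
  if (any(!is.finite(clint)) || any(clint <= 0)) {
    abort("`clint` must be strictly positive.", class = "cypivive_domain_error")
  }
  vmax / clint
}

#' Predict activities of five CYPs for a cohort from four measured CYPs
#'
#' Applies the registry's descriptive models per subject to fill `V_max` and
#' `CL_int` for CYP2A6, 2C8, 2D6, 2E1 and 3A4/5 from the measured activities
#' of CYP1A2, 2B6, 2C9 and 2C19, then derives `K_m = V_max / CL_int`
#' ([derive_km()]). The registry's `K_m` regression (3A4/5) is deliberately
#' not used: the ratio identity keeps the three parameters mutually
#' consistent and cannot go negative.
#'
#' Subjects missing a required predictor are dropped for that response with a
#' message. Negative regression outputs propagate unclamped (with a warning)
#' and `K_m` is only derived where both `V_max` and `CL_int` are positive.
#'
#' @param measured Long activity table: `subject_id`, `cyp`, `parameter`
#'   (`"vmax"`/`"clint"`; `"km"` rows are ignored), `value`. Must contain the
#'   predictors required by the registry models.
#' @param registry A `cyp_registry`; defaults to [published_models()].
#' @param targets Response CYPs to predict; default the five standard targets.
#' @return A long tibble `subject_id`, `cyp`, `parameter`, `value` covering
#'   `vmax`, `clint` and `km` for each target CYP.
#' @examples
#' med <- published_activity_summary() |>
#'   dplyr::filter(cyp %in% c("1A2", "2B6", "2C9", "2C19"),
#'                 parameter != "km") |>
#'   dplyr::transmute(subject_id = "median-donor", cyp, parameter,
#'                    value = median)
#' predict_cohort(med)
#' @export
predict_cohort <- function(measured, registry = published_models(),
                           targets = predicted_cyps()) {
  required <- c("subject_id", "cyp", "parameter", "value")
  missing_cols <- setdiff(required, names(measured))
  if (length(missing_cols) > 0) {
    abort(paste0("`measured` lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "cypivive_input_error")
  }
  if (nrow(measured) == 0) {
    return(tibble::tibble(subject_id = character(), cyp = character(),
                          parameter = character(), value = double()))
  }
  subjects <- unique(measured$subject_id)

  predict_one <- function(target, param) {
    model <- registry_get(registry, target, param)
    wide <- measured %>%
      dplyr::filter(.data$parameter == !!param,
                    .data$cyp %in% names(model$terms)) %>%
      dplyr::select("subject_id", "cyp", "value") %>%
      tidyr::pivot_wider(names_from = "cyp", values_from = "value")
    missing_preds <- setdiff(names(model$terms), names(wide))
    if (length(missing_preds) > 0) {
      abort(sprintf("Measured table lacks %s values for predictor(s): %s",
                    param, paste(missing_preds, collapse = ", ")),
            class = "cypivive_input_error")
    }
    ok <- stats::complete.cases(wide[, names(model$terms), drop = FALSE])
    if (any(!ok)) {
      inform(sprintf("%s(%s): dropped %d subject(s) with missing predictors.",
                     param, target, sum(!ok)))
      wide <- wide[ok, , drop = FALSE]
    }
    tibble::tibble(
      subject_id = wide$subject_id,
      cyp = target,
      parameter = param,
      value = apply_model(model, as.list(wide[, names(model$terms), drop = FALSE]))
    )
  }

  out <- tidyr::expand_grid(target = targets, param = c("vmax", "clint")) %>%
    purrr::pmap(function(target, param) predict_one(target, param)) %>%
    purrr::list_rbind()

  km <- out %>%
    tidyr::pivot_wider(names_from = "parameter", values_from = "value") %>%
    dplyr::filter(!is.na(.data$vmax), !is.na(.data$clint), .data$clint > 0) %>%
    dplyr::transmute(.data$subject_id, .data$cyp, parameter = "km",
                     value = derive_km(.data$vmax, .data$clint))

  dplyr::bind_rows(out, km) %>%
    dplyr::arrange(match(.data$subject_id, subjects),
                   match(.data$cyp, cyp_isoforms()),
                   match(.data$parameter, kinetic_parameters()))
}

#' Smallest set of measured CYPs covering every response model
#'
#' Finds the minimum-cardinality set `M` of CYPs such that every response has
#' at least one candidate model whose predictors are all contained in `M`.
#' The search is exhaustive over subsets of the predictor universe (at most
#' ten CYPs), enumerated by size and then lexicographically, so ties break
#' toward the lexicographically first set.
#'
#' @param x Either a `cyp_registry` (each registered model is the sole
#'   candidate for its `(cyp, parameter)` response) or a named list mapping a
#'   response label to a list of candidate [cyp_model()]s.
#' @return Character vector: the minimal measured set, sorted.
#' @examples
#' reg <- published_models()
#' minimal_predictor_set(reg[reg$parameter != "km", ])
#' @export
minimal_predictor_set <- function(x) {
  families <- if (inherits(x, "cyp_registry")) {
    split(x$model, paste(x$cyp, x$parameter, sep = "/"))
  } else {
    x
  }
  if (length(families) == 0) {
    abort("No response models supplied.", class = "cypivive_input_error")
  }
  pred_sets <- purrr::map(families, function(cands) {
    purrr::map(cands, ~ names(.x$terms))
  })
  universe <- sort(unique(unlist(pred_sets)))
  covers <- function(set) {
    purrr::every(pred_sets, function(cands) {
      purrr::some(cands, ~ all(.x %in% set))
    })
  }
  for (size in 0:length(universe)) {
    if (size == 0) {
      if (covers(character())) return(character())
      next
    }
    combos <- utils::combn(universe, size, simplify = FALSE)
    for (s in combos) {
      if (covers(s)) return(s)
    }
  }
  abort("No covering predictor set exists for the supplied model families.",
        class = "cypivive_infeasible")
}
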
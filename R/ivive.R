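#' Hepatic blood flow from cardiac output
#'
#' The liver receives 24.5% of cardiac output: `Q_H = 0.245 * CO`.
#'
#' @param cardiac_output Cardiac output, ml/min (> 0). Vectorised.
#' @return Hepatic blood flow `Q_H`, ml/min.
#' @examples
#' hepatic_blood_flow(5140)
#' @export
hepatic_blood_flow <- function(cardiac_output) {
  assert_positive(cardiac_output, "cardiac_output")
  0.245 * cardiac_output
}

#' Liver weight from body weight
#'
#' Liver volume (ml) is `12.5 * BW + 536.4` with BW in kg; weight follows
#' with a liver density of 1.001 g/ml.
#'
#' @param bw Body weight, kg (> 0). Vectorised.
#' @return Liver weight, g.
#' @examples
#' liver_weight(64)
#' @export
liver_weight <- function(bw) {
  assert_positive(bw, "bw")
  (12.5 * bw + 536.4) * 1.001
}

#' Whole-liver unbound scaled intrinsic clearance
#'
#' Scales a per-mg-microsomal-protein intrinsic clearance to the whole organ
#' and to unbound drug in blood:
#' `X = CL_int * MPPGL * LW * (f_u,p / R_B) / 1000` (ul to ml), giving an
#' absolute flow in ml/min comparable with hepatic blood flow. With
#' `per_bw = TRUE` the literal per-body-weight variant `X / BW` is returned
#' instead (see the methods vignette for why the absolute-flow form is the
#' default).
#'
#' @param clint Intrinsic clearance, ul/min/mg protein (>= 0). Vectorised.
#' @param mppgl Microsomal protein per gram liver, mg/g (> 0).
#' @param lw Liver weight, g (> 0).
#' @param fu_p Plasma unbound fraction, (0, 1].
#' @param rb Blood-to-plasma concentration ratio (> 0).
#' @param per_bw If `TRUE`, divide by `bw` (kg), yielding ml/min/kg.
#' @param bw Body weight, kg; required when `per_bw = TRUE`.
#' @return Unbound scaled intrinsic clearance `X`, ml/min (or ml/min/kg).
#' @examples
#' scaled_intrinsic_clearance(507.5, 39.6, 1337.2, 0.042, 0.54)
#' @export
scaled_intrinsic_clearance <- function(clint, mppgl, lw, fu_p, rb,
                                       per_bw = FALSE, bw = NULL) {
  if (any(!is.finite(clint)) || any(clint < 0)) {
    abort("`clint` must be non-negative.", class = "cypivive_domain_error")
  }
  assert_positive(mppgl, "mppgl")
  assert_positive(lw, "lw")
  assert_positive(fu_p, "fu_p")
  assert_positive(rb, "rb")
  x <- clint * mppgl * lw * (fu_p / rb) / 1000
  if (per_bw) {
    if (is.null(bw)) {
      abort("`bw` is required when `per_bw = TRUE`.",
            class = "cypivive_input_error")
    }
    assert_positive(bw, "bw")
    x <- x / bw
  }
  x
}

#' Bias-corrected well-stirred hepatic clearance
#'
#' The conventional bias-corrected IVIVE (CBC-IVIVE) clearance is the
#' well-stirred model scaled by a drug-specific correction coefficient:
#' `CL_H = CC * Q_H * X / (Q_H + X)`, where `X` is the unbound scaled
#' intrinsic clearance ([scaled_intrinsic_clearance()]). As `X` grows, `CL_H`
#' approaches the flow-limited ceiling `CC * Q_H`.
#'
#' @param cc Correction coefficient, dimensionless (> 0). Vectorised.
#' @param qh Hepatic blood flow, ml/min (> 0).
#' @param x Unbound scaled intrinsic clearance, ml/min (>= 0).
#' @return Hepatic clearance `CL_H`, ml/min.
#' @examples
#' cbc_ivive_clearance(0.540, 1259.3, 2090)
#' @export
cbc_ivive_clearance <- function(cc, qh, x) {
  assert_positive(cc, "cc")
  assert_positive(qh, "qh")
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("`x` must be non-negative.", class = "cypivive_domain_error")
  }
  cc * qh * x / (qh + x)
}

#' Extrapolate in-vivo hepatic clearance for a cohort
#'
#' Composes [scaled_intrinsic_clearance()] and [cbc_ivive_clearance()] per
#' subject per probe drug, using each drug's responsible CYP's `CL_int` from
#' the activity table.
#'
#' @param activities Long activity table (`subject_id`, `cyp`, `parameter`,
#'   `value`) holding `clint` rows for the CYPs the drugs map to; typically
#'   measured activities from [fit_kinetics()] or predictions from
#'   [predict_cohort()].
#' @param physiology Per-subject tibble with columns `subject_id`, `bw_kg`,
#'   `mppgl_mg_g` and either `qh_ml_min` or `cardiac_output_ml_min` (and
#'   optionally `lw_g`; derived from body weight when absent).
#' @param drugs Drug parameter table, defaulting to [published_drugs()].
#' @param clint_source Label recorded in the result (`"measured"` or
#'   `"predicted"`); purely descriptive.
#' @param per_bw Use the literal per-body-weight scaling variant (audit aid);
#'   default `FALSE` (absolute flow units).
#' @return A tibble with one row per subject x drug: `subject_id`, `drug`,
#'   `cyp`, `clint_source`, `x_ml_min`, `clh_ml_min`. Subjects lacking the
#'   required `CL_int` are skipped with a message.
#' @examples
#' phys <- tibble::tibble(subject_id = "median-donor", bw_kg = 64,
#'                        cardiac_output_ml_min = 5140, mppgl_mg_g = 39.6)
#' act <- tibble::tibble(subject_id = "median-donor", cyp = "3A4/5",
#'                       parameter = "clint", value = 507.5)
#' extrapolate_cohort(act, phys, clint_source = "predicted")
#' @export
extrapolate_cohort <- function(activities, physiology,
                               drugs = published_drugs(),
                               clint_source = c("measured", "predicted"),
                               per_bw = FALSE) {
  clint_source <- match.arg(clint_source)
  need_phys <- c("subject_id", "bw_kg", "mppgl_mg_g")
  missing_cols <- setdiff(need_phys, names(physiology))
  if (length(missing_cols) > 0) {
    abort(paste0("`physiology` lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "cypivive_input_error")
  }
  phys <- tibble::as_tibble(physiology)
  if (!"qh_ml_min" %in% names(phys)) {
    if (!"cardiac_output_ml_min" %in% names(phys)) {
      abort("`physiology` needs `qh_ml_min` or `cardiac_output_ml_min`.",
            class = "cypivive_input_error")
    }
    phys$qh_ml_min <- hepatic_blood_flow(phys$cardiac_output_ml_min)
  }
  if (!"lw_g" %in% names(phys)) phys$lw_g <- liver_weight(phys$bw_kg)

  if (nrow(drugs) == 0) {
    return(tibble::tibble(subject_id = character(), drug = character(),
                          cyp = character(), clint_source = character(),
                          x_ml_min = double(), clh_ml_min = double()))
  }

  clint_tbl <- activities %>%
    dplyr::filter(.data$parameter == "clint") %>%
    dplyr::select("subject_id", "cyp", clint = "value")

  grid <- tidyr::crossing(subject_id = phys$subject_id,
                          drug = drugs$drug) %>%
    dplyr::left_join(drugs, by = "drug") %>%
    dplyr::left_join(phys, by = "subject_id") %>%
    dplyr::left_join(clint_tbl, by = c("subject_id", "cyp"))

  skipped <- sum(is.na(grid$clint))
  if (skipped > 0) {
    inform(sprintf("Skipped %d subject-drug pair(s) lacking CL_int.", skipped))
    grid <- grid[!is.na(grid$clint), , drop = FALSE]
  }
  if (nrow(grid) == 0) {
    return(tibble::tibble(subject_id = character(), drug = character(),
                          cyp = character(), clint_source = character(),
                          x_ml_min = double(), clh_ml_min = double()))
  }

  n_neg <- sum(grid$clint < 0)
  if (n_neg > 0) {
    warn(sprintf("%d negative CL_int value(s) floored at 0 for extrapolation.",
                 n_neg),
         class = "cypivive_negative_clint")
  }

  grid %>%
    dplyr::mutate(
      x_ml_min = scaled_intrinsic_clearance(
        pmax(.data$clint, 0), .data$mppgl_mg_g, .data$lw_g,
        .data$fu_p, .data$rb, per_bw = per_bw,
        bw = if (per_bw) .data$bw_kg else NULL
      ),
      clh_ml_min = cbc_ivive_clearance(.data$cc, .data$qh_ml_min,
                                       .data$x_ml_min),
      clint_source = clint_source
    ) %>%
    dplyr::select("subject_id", "drug", "cyp", "clint_source",
                  "x_ml_min", "clh_ml_min")
}
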
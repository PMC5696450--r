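# Published cohort summaries shipped as reference data. These are the
# calibration targets for the synthetic cohort generator and the inputs to
# the worked examples; they summarise a 105-donor human-liver-microsome
# bank (median and range per CYP and kinetic parameter).

#' Published summary of measured CYP activities in human liver microsomes
#'
#' Median and range of `V_max` (pmol/min/mg protein), `K_m` (uM) and `CL_int`
#' (ul/min/mg protein) for ten CYP isoforms measured with probe-substrate
#' assays in a bank of 105 normal human liver microsome preparations. These
#' values calibrate [generate_cohort()] and drive the worked examples.
#'
#' @return A tibble with columns `cyp`, `parameter` (`vmax`/`km`/`clint`),
#'   `median`, `min`, `max`.
#' @examples
#' published_activity_summary()
#' @export
published_activity_summary <- function() {
  tribble_rows <- list(
    # cyp,    vmax: med, min, max,        km: med, min, max,      clint: med, min, max
    list("1A2",   754.9,  94.9, 3154.0,   54.7,  4.7, 181.6,   14.5,  2.8,   67.2),
    list("2A6",   354.4,   3.7, 3295.0,    2.3,  0.8,  10.0,  145.0,  1.2,  544.7),
    list("2B6",    53.3,  12.8,  333.5,   73.4, 17.1, 393.3,    0.77, 0.13,   5.22),
    list("2C8",    37.5,   2.8,  174.6,   14.3,  7.0,  38.9,    2.70, 0.09,   6.19),
    list("2C9",   256.2,  83.8,  454.8,  219.2, 101.2, 555.3,   1.17, 0.17,   4.18),
    list("2C19",  103.9,   2.3,  381.4,   59.7, 20.6, 198.3,    1.91, 0.01,   7.46),
    list("2D6",   113.3,  23.5, 1041.0,   28.9,  6.5, 260.6,    3.5,  0.2,   39.5),
    list("2E1",   532.1, 163.1, 1982.0,   52.5, 27.1, 177.2,   10.5,  1.9,   39.0),
    list("3A4/5", 788.0,  69.4, 5035.0,    1.9,  0.4,  10.2,  464.6,  8.3, 1673.5)
  )
  purrr::map_dfr(tribble_rows, function(r) {
    tibble::tibble(
      cyp = r[[1]],
      parameter = c("vmax", "km", "clint"),
      median = c(r[[2]], r[[5]], r[[8]]),
      min = c(r[[3]], r[[6]], r[[9]]),
      max = c(r[[4]], r[[7]], r[[10]])
    )
  })
}

#' Published summary of model-predicted CYP activities
#'
#' Median, range and 95% prediction interval of the `V_max`, `K_m` and
#' `CL_int` values obtained by applying the published descriptive models
#' ([published_models()]) across the 105-donor cohort. `K_m` rows are derived
#' as `V_max / CL_int`.
#'
#' @return A tibble with columns `cyp`, `parameter`, `median`, `min`, `max`,
#'   `pi_low`, `pi_high`.
#' @examples
#' published_predicted_summary()
#' @export
published_predicted_summary <- function() {
  rows <- list(
    list("2A6",  "vmax",  344.4, 110.3,  979.1, 154.5,  857.4),
    list("2A6",  "km",      2.5,   0.9,    5.4,   1.3,    5.1),
    list("2A6",  "clint", 138.9, 120.5,  192.5, 122.9,  176.7),
    list("2C8",  "vmax",   42.3,   8.4,   84.0,  12.7,   76.9),
    list("2C8",  "km",     15.0,   4.5,   30.3,   6.8,   23.9),
    list("2C8",  "clint",   2.7,   1.8,    5.3,   1.9,    4.4),
    list("2D6",  "vmax",  133.9,  51.0,  229.5,  52.7,  216.5),
    list("2D6",  "km",     29.6,  10.0,   49.0,  11.3,   46.4),
    list("2D6",  "clint",   4.4,   3.5,   10.8,   3.6,    8.0),
    list("2E1",  "vmax",  581.8, 390.3, 1227.5, 421.8, 1115.5),
    list("2E1",  "km",     53.9,  30.8,   93.2,  36.4,   71.9),
    list("2E1",  "clint",  11.0,   7.2,   18.7,   7.9,   17.3),
    list("3A4/5", "vmax", 897.7, 302.7, 3493.1, 434.3, 1837.2),
    list("3A4/5", "km",     1.8,   0.7,    4.6,   1.0,    4.3),
    list("3A4/5", "clint", 507.5, 235.9, 958.3, 278.6,  871.5)
  )
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(cyp = r[[1]], parameter = r[[2]], median = r[[3]],
                   min = r[[4]], max = r[[5]], pi_low = r[[6]], pi_high = r[[7]])
  })
}

#' Published cohort physiology summary
#'
#' Medians and ranges of the physiological quantities entering the CBC-IVIVE
#' scaling for the 105-donor cohort: hepatic blood flow `Q_H` (ml/min),
#' microsomal protein per gram liver `MPPGL` (mg/g), liver weight `LW` (g)
#' and body weight `BW` (kg).
#'
#' @return A tibble with columns `quantity`, `unit`, `median`, `min`, `max`.
#' @examples
#' published_physiology_summary()
#' @export
published_physiology_summary <- function() {
  tibble::tibble(
    quantity = c("qh", "mppgl", "lw", "bw"),
    unit = c("ml/min", "mg/g", "g", "kg"),
    median = c(1259.3, 39.6, 1337.2, 64.0),
    min = c(1205.4, 9.9, 912.3, 30.0),
    max = c(1629.3, 127.9, 1688.1, 92.0)
  )
}

#' Published drug parameters for CBC-IVIVE extrapolation
#'
#' Correction coefficient (CC), plasma unbound fraction (`f_u,p`),
#' blood-to-plasma ratio (`R_B`), literature-observed in-vivo clearance
#' (mean +/- SD, ml/min) and report counts for the five probe drugs, each
#' mapped to the CYP that clears it (coumarin to 2A6, paclitaxel to 2C8,
#' dextromethorphan to 2D6, chlorzoxazone to 2E1, midazolam to 3A4/5).
#'
#' @param path Optional path to an alternative drug-parameter CSV with the
#'   same columns; defaults to the packaged file.
#' @return A tibble with columns `drug`, `cyp`, `cc`, `fu_p`, `rb`,
#'   `observed_clh_mean`, `observed_clh_sd`, `n_reports`.
#' @examples
#' published_drugs()
#' @export
published_drugs <- function(path = NULL) {
  path <- path %||% system.file("extdata", "drug_ivive_params.csv",
                                package = "cypivive", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("drug", "cyp", "cc", "fu_p", "rb",
                "observed_clh_mean", "observed_clh_sd", "n_reports")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0("Drug-parameter file lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "cypivive_input_error")
  }
  if (any(out$fu_p <= 0 | out$fu_p > 1) || any(out$rb <= 0) || any(out$cc <= 0)) {
    abort("Drug parameters out of range: need 0 < fu_p <= 1, rb > 0, cc > 0.",
          class = "cypivive_domain_error")
  }
  out
}
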
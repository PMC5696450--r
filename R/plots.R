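#' Plot a Michaelis-Menten fit
#'
#' Observed velocities with the fitted hyperbola overlaid.
#'
#' @param object An [mm_fit()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mm_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(
    substrate_conc_uM = exp(seq(log(min(dat$substrate_conc_uM)),
                                log(max(dat$substrate_conc_uM)),
                                length.out = 200))
  )
  grid$velocity_pmol_min_mg <- object$vmax * grid$substrate_conc_uM /
    (object$km + grid$substrate_conc_uM)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$substrate_conc_uM,
                                    y = .data$velocity_pmol_min_mg)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Substrate concentration (uM)",
      y = "Velocity (pmol/min/mg protein)",
      title = sprintf("V_max = %.3g, K_m = %.3g, CL_int = %.3g",
                      object$vmax, object$km, object$clint)
    ) +
    ggplot2::theme_minimal()
}

#' Plot activity distributions of a synthetic cohort
#'
#' Log-scale boxplots of one kinetic parameter across the ten CYPs, a quick
#' visual check of the generator's calibration.
#'
#' @param object A `cyp_cohort` from [generate_cohort()].
#' @param parameter Kinetic parameter to display (default `"clint"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cyp_cohort <- function(object, parameter = "clint", ...) {
  parameter <- match.arg(parameter, kinetic_parameters())
  dat <- object$activities %>%
    dplyr::filter(.data$parameter == !!parameter) %>%
    dplyr::mutate(cyp = factor(.data$cyp, levels = cyp_isoforms()))
  unit <- c(vmax = "pmol/min/mg", km = "uM", clint = "ul/min/mg")[[parameter]]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cyp, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey90") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = sprintf("%s (%s)", parameter, unit)) +
    ggplot2::theme_minimal()
}

#' Fold-error dot plot for extrapolated clearances
#'
#' Individual fold-errors (predicted individual clearance over the geometric
#' mean of observed report means) per drug and `CL_int` source, with the
#' 0.5-2 acceptance window shaded.
#'
#' @param results Clearance results from [extrapolate_cohort()] (one or both
#'   sources).
#' @param drugs Drug parameter table, default [published_drugs()].
#' @return A ggplot.
#' @export
plot_fold_error <- function(results, drugs = published_drugs()) {
  dat <- results %>%
    dplyr::inner_join(drugs %>% dplyr::select("drug", "observed_clh_mean"),
                      by = "drug") %>%
    dplyr::filter(.data$clh_ml_min > 0) %>%
    dplyr::mutate(ife = .data$clh_ml_min / .data$observed_clh_mean)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$clint_source, y = .data$ife)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0.5, ymax = 2,
                      alpha = 0.15, fill = "seagreen") +
    ggplot2::geom_jitter(width = 0.15, size = 0.7, alpha = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~drug, nrow = 1) +
    ggplot2::labs(x = "CL_int source", y = "Individual fold-error") +
    ggplot2::theme_minimal()
}
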
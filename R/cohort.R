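# Synthetic cohort generation. The generator reproduces the statistical
# structure the analysis assumes: right-skewed (lognormal) activity and
# physiology marginals calibrated to published medians/ranges, and
# cross-CYP correlation induced solely by the published linear model
# backbone plus independent Gaussian noise whose variance is set so the
# population R^2 matches each model's published R^2.

# Probe-substrate incubation grids (uM): printed endpoints of the serial
# two-fold dilution series used per CYP.
probe_grid_table <- function() {
  tibble::tibble(
    cyp = c("1A2", "2A6", "2B6", "2C8", "2C9", "2C19", "2D6", "2E1", "3A4/5"),
    probe = c("phenacetin", "coumarin", "bupropion", "paclitaxel",
              "tolbutamide", "omeprazole", "dextromethorphan",
              "chlorzoxazone", "midazolam"),
    s_min = c(6.25, 0.156, 7.8, 2.5, 31.25, 3.9, 0.625, 7.8, 0.39),
    s_max = c(800, 20, 500, 80, 2000, 500, 960, 1000, 50)
  )
}

substrate_grid <- function(cyp) {
  tab <- probe_grid_table()
  row <- tab[tab$cyp == cyp, ]
  if (nrow(row) != 1) {
    abort(sprintf("No probe substrate grid defined for CYP '%s'.", cyp),
          class = "cypivive_config_error")
  }
  n_pts <- min(8L, max(6L, floor(log2(row$s_max / row$s_min)) + 1L))
  exp(seq(log(row$s_min), log(row$s_max), length.out = n_pts))
}

#' Simulate one probe-substrate incubation series
#'
#' Generates velocities `v = V_max * S / (K_m + S) * (1 + e)` with
#' multiplicative Gaussian noise `e ~ N(0, noise_cv^2)` on the CYP's probe
#' substrate concentration grid (a 6-8 point serial dilution between the
#' assay's published endpoints, e.g. 0.39-50 uM midazolam for CYP3A4/5).
#'
#' @param vmax,km True Michaelis-Menten parameters (pmol/min/mg, uM).
#' @param cyp CYP isoform selecting the substrate grid.
#' @param noise_cv Coefficient of variation of the multiplicative noise;
#'   `0` yields exact model values.
#' @param seed Optional integer seed (local to this call).
#' @return A tibble `cyp`, `probe`, `substrate_conc_uM`,
#'   `velocity_pmol_min_mg`.
#' @examples
#' generate_kinetic_curves(100, 10, cyp = "2C9", noise_cv = 0, seed = 1)
#' @export
generate_kinetic_curves <- function(vmax, km, cyp, noise_cv = 0.05,
                                    seed = NULL) {
  assert_positive(vmax, "vmax")
  assert_positive(km, "km")
  if (noise_cv < 0) {
    abort("`noise_cv` must be non-negative.", class = "cypivive_domain_error")
  }
  s <- substrate_grid(cyp)
  probe <- probe_grid_table()$probe[probe_grid_table()$cyp == cyp]
  with_local_seed(seed, {
    v <- vmax * s / (km + s)
    if (noise_cv > 0) v <- v * (1 + rnorm(length(s), 0, noise_cv))
    tibble::tibble(cyp = cyp, probe = probe, substrate_conc_uM = s,
                   velocity_pmol_min_mg = pmax(v, 0))
  })
}

draw_calibrated_lognormal <- function(n, median, min, max) {
  par <- calibrate_lognormal(median, min, max)
  rlnorm_trunc(n, par$meanlog, par$sdlog, min, max)
}

#' Generate a synthetic liver-donor cohort
#'
#' Draws demographics, physiology and a ten-CYP activity table with the
#' structure the downstream pipeline expects:
#'
#' 1. gender (female fraction 0.648) and demographic covariates;
#' 2. body weight from a truncated lognormal calibrated to median 64.0 kg,
#'    range 30.0-92.0 kg; liver weight via [liver_weight()];
#' 3. cardiac output from gender-specific truncated normals calibrated so
#'    hepatic blood flow ([hepatic_blood_flow()]) has median ~1259.3 and
#'    range 1205.4-1629.3 ml/min; MPPGL from a truncated lognormal
#'    (median 39.6, range 9.9-127.9 mg/g);
#' 4. the four measured "driver" CYPs' `V_max` and `CL_int` as independent
#'    truncated lognormals matching the published medians/ranges, with
#'    `K_m = V_max / CL_int`;
#' 5. the five remaining CYPs' `V_max` and `CL_int` from the registry's
#'    linear models plus Gaussian noise whose variance is chosen so the
#'    population `R^2` equals each model's published `R^2` (non-positive
#'    draws are redrawn, at most 100 times each); again `K_m = V_max/CL_int`.
#'
#' @param n_subjects Cohort size (default 105, the reference study size).
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @param female_fraction Probability a subject is female.
#' @param activity_calibration Per-CYP median/min/max table, defaulting to
#'   [published_activity_summary()].
#' @param registry Generative model backbone, default [published_models()].
#' @param physiology_calibration Default [published_physiology_summary()].
#' @return An object of class `cyp_cohort`: a list of tibbles `covariates`
#'   (`subject_id`, `gender`, `age_group`, `smoking`, `drinking`),
#'   `physiology` (`subject_id`, `bw_kg`, `cardiac_output_ml_min`,
#'   `qh_ml_min`, `lw_g`, `mppgl_mg_g`) and `activities` (long table
#'   `subject_id`, `cyp`, `parameter`, `value` for all ten CYPs).
#' @examples
#' cohort <- generate_cohort(n_subjects = 20, seed = 1)
#' dplyr::glimpse(cohort$physiology)
#' @export
generate_cohort <- function(n_subjects = 105, seed = NULL,
                            female_fraction = 0.648,
                            activity_calibration = published_activity_summary(),
                            registry = published_models(),
                            physiology_calibration = published_physiology_summary()) {
  if (n_subjects < 0 || n_subjects != round(n_subjects)) {
    abort("`n_subjects` must be a non-negative integer.",
          class = "cypivive_input_error")
  }
  if (female_fraction <= 0 || female_fraction >= 1) {
    abort("`female_fraction` must be in (0, 1).",
          class = "cypivive_config_error")
  }
  bad <- activity_calibration$median < activity_calibration$min |
    activity_calibration$median > activity_calibration$max
  if (any(bad)) {
    abort("Calibration medians must lie inside their ranges.",
          class = "cypivive_config_error")
  }

  empty <- function() {
    structure(list(
      covariates = tibble::tibble(subject_id = character(),
                                  gender = character(),
                                  age_group = character(),
                                  smoking = logical(), drinking = logical()),
      physiology = tibble::tibble(subject_id = character(), bw_kg = double(),
                                  cardiac_output_ml_min = double(),
                                  qh_ml_min = double(), lw_g = double(),
                                  mppgl_mg_g = double()),
      activities = tibble::tibble(subject_id = character(), cyp = character(),
                                  parameter = character(), value = double())
    ), class = "cyp_cohort")
  }
  if (n_subjects == 0) return(empty())

  phys_cal <- function(q) {
    physiology_calibration[physiology_calibration$quantity == q, ]
  }
  act_cal <- function(cy, par) {
    activity_calibration[activity_calibration$cyp == cy &
                           activity_calibration$parameter == par, ]
  }

  with_local_seed(seed, {
    n <- n_subjects
    subject_id <- sprintf("S%04d", seq_len(n))

    ## demographics
    gender <- ifelse(runif(n) < female_fraction, "female", "male")
    age_group <- sample(c("<44", "45-59", "60-74", ">75"), n, replace = TRUE,
                        prob = c(35, 56, 13, 1) / 105)
    smoking <- runif(n) < 12 / 101
    drinking <- runif(n) < 12 / 101
    if (n >= 8) {
      smoking[sample.int(n, 4)] <- NA
      drinking[sample.int(n, 4)] <- NA
    }

    ## physiology
    bw_row <- phys_cal("bw")
    bw <- draw_calibrated_lognormal(n, bw_row$median, bw_row$min, bw_row$max)
    lw <- liver_weight(bw)
    qh_row <- phys_cal("qh")
    co_min <- qh_row$min / 0.245
    co_max <- qh_row$max / 0.245
    co <- ifelse(gender == "female",
                 rnorm_trunc(n, 4930, 250, co_min, co_max),
                 rnorm_trunc(n, 5150, 400, co_min, co_max))
    qh <- hepatic_blood_flow(co)
    mp_row <- phys_cal("mppgl")
    mppgl <- draw_calibrated_lognormal(n, mp_row$median, mp_row$min, mp_row$max)

    physiology <- tibble::tibble(
      subject_id = subject_id, bw_kg = bw, cardiac_output_ml_min = co,
      qh_ml_min = qh, lw_g = lw, mppgl_mg_g = mppgl
    )

    ## driver CYP activities: independent truncated lognormals
    drivers <- purrr::map(setNames(nm = measured_cyps()), function(cy) {
      vm_row <- act_cal(cy, "vmax")
      cl_row <- act_cal(cy, "clint")
      vmax <- draw_calibrated_lognormal(n, vm_row$median, vm_row$min, vm_row$max)
      clint <- draw_calibrated_lognormal(n, cl_row$median, cl_row$min, cl_row$max)
      tibble::tibble(vmax = vmax, clint = clint, km = vmax / clint)
    })

    ## target CYP activities from the linear backbone + calibrated noise
    target_value <- function(cy, par) {
      model <- registry_get(registry, cy, par)
      inputs <- purrr::map(setNames(nm = names(model$terms)),
                           function(p) drivers[[p]][[par]])
      lin <- apply_model(model, inputs, quiet = TRUE)
      r2 <- model$r2
      sigma <- if (is.finite(r2) && r2 > 0 && r2 < 1 && n >= 2 && var(lin) > 0) {
        sqrt(var(lin) * (1 - r2) / r2)
      } else {
        0
      }
      y <- lin + rnorm(n, 0, sigma)
      bad <- which(y <= 0)
      for (i in bad) {
        tries <- 0L
        while (y[i] <= 0) {
          tries <- tries + 1L
          if (tries > 100L) {
            abort(sprintf("Could not draw a positive %s(%s) after 100 redraws; calibration infeasible.",
                          par, cy),
                  class = "cypivive_config_error")
          }
          y[i] <- lin[i] + rnorm(1, 0, sigma)
        }
      }
      y
    }
    targets <- purrr::map(setNames(nm = predicted_cyps()), function(cy) {
      vmax <- target_value(cy, "vmax")
      clint <- target_value(cy, "clint")
      tibble::tibble(vmax = vmax, clint = clint, km = vmax / clint)
    })

    all_cyps <- c(drivers, targets)
    activities <- purrr::imap(all_cyps, function(df, cy) {
      tibble::tibble(
        subject_id = rep(subject_id, 3),
        cyp = cy,
        parameter = rep(c("vmax", "km", "clint"), each = n),
        value = c(df$vmax, df$km, df$clint)
      )
    }) %>%
      purrr::list_rbind() %>%
      dplyr::arrange(match(.data$subject_id, subject_id),
                     match(.data$cyp, cyp_isoforms()),
                     match(.data$parameter, kinetic_parameters()))

    structure(list(
      covariates = tibble::tibble(subject_id = subject_id, gender = gender,
                                  age_group = age_group, smoking = smoking,
                                  drinking = drinking),
      physiology = physiology,
      activities = activities
    ), class = "cyp_cohort")
  })
}

#' @export
print.cyp_cohort <- function(x, ...) {
  cat(sprintf("<cyp_cohort: %d subjects, %d activity records>\n",
              nrow(x$physiology), nrow(x$activities)))
  invisible(x)
}
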
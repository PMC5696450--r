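test_that("empty and deterministic generation contracts hold", {
  empty <- generate_cohort(0, seed = 1)
  expect_equal(nrow(empty$physiology), 0L)
  expect_equal(nrow(empty$activities), 0L)
  a <- generate_cohort(40, seed = 123)
  b <- generate_cohort(40, seed = 123)
  expect_identical(a, b)
  c <- generate_cohort(40, seed = 124)
  expect_false(identical(a$activities$value, c$activities$value))
  expect_error(generate_cohort(-1), class = "cypivive_input_error")
  expect_error(generate_cohort(5, female_fraction = 1.2),
               class = "cypivive_config_error")
})

test_that("every generated subject satisfies the kinetic ratio identity", {
  cohort <- generate_cohort(30, seed = 2)
  wide <- tidyr::pivot_wider(cohort$activities, names_from = parameter,
                             values_from = value)
  expect_true(all(wide$vmax > 0 & wide$km > 0 & wide$clint > 0))
  expect_equal(wide$clint, wide$vmax / wide$km, tolerance = 1e-12)
})

test_that("generated physiology respects its invariants and calibration", {
  cohort <- generate_cohort(10000, seed = 3)
  ph <- cohort$physiology
  expect_true(all(ph$qh_ml_min == 0.245 * ph$cardiac_output_ml_min))
  expect_equal(ph$lw_g, (12.5 * ph$bw_kg + 536.4) * 1.001)
  cal <- published_physiology_summary()
  tgt <- function(q, col) cal[[col]][cal$quantity == q]
  expect_true(all(ph$bw_kg >= tgt("bw", "min") & ph$bw_kg <= tgt("bw", "max")))
  expect_true(all(ph$qh_ml_min >= tgt("qh", "min") - 1e-9 &
                    ph$qh_ml_min <= tgt("qh", "max") + 1e-9))
  expect_true(all(ph$mppgl_mg_g >= tgt("mppgl", "min") &
                    ph$mppgl_mg_g <= tgt("mppgl", "max")))
  # medians land on the published targets at Monte-Carlo precision
  expect_lt(abs(median(ph$bw_kg) - 64.0) / 64.0, 0.03)
  expect_lt(abs(median(ph$mppgl_mg_g) - 39.6) / 39.6, 0.03)
  expect_lt(abs(median(ph$qh_ml_min) - 1259.3) / 1259.3, 0.03)
  # gender mix
  expect_lt(abs(mean(cohort$covariates$gender == "female") - 0.648), 0.02)
})

test_that("driver CYP activity medians match their published calibration", {
  cohort <- generate_cohort(10000, seed = 4)
  acts <- cohort$activities
  med <- function(cy, par) {
    median(acts$value[acts$cyp == cy & acts$parameter == par])
  }
  expect_lt(abs(med("2C9", "clint") - 1.17) / 1.17, 0.03)
  expect_lt(abs(med("2C19", "clint") - 1.91) / 1.91, 0.03)
  expect_lt(abs(med("1A2", "vmax") - 754.9) / 754.9, 0.03)
  expect_lt(abs(med("2B6", "clint") - 0.77) / 0.77, 0.03)
  # ranges respected by construction
  cal <- published_activity_summary()
  for (cy in c("1A2", "2B6", "2C9", "2C19")) {
    for (par in c("vmax", "clint")) {
      v <- acts$value[acts$cyp == cy & acts$parameter == par]
      lo <- cal$min[cal$cyp == cy & cal$parameter == par]
      hi <- cal$max[cal$cyp == cy & cal$parameter == par]
      expect_true(all(v >= lo & v <= hi))
    }
  }
})

test_that("the linear backbone induces the published correlation structure", {
  cohort <- generate_cohort(10000, seed = 5)
  w <- tidyr::pivot_wider(
    dplyr::filter(cohort$activities, parameter == "clint",
                  cyp %in% c("2C8", "2C9")),
    names_from = cyp, values_from = value
  )
  fit <- lm(`2C8` ~ `2C9`, data = w)
  # sample R2 close to the published population target
  expect_lt(abs(summary(fit)$r.squared - 0.235), 0.03)
  # The positivity redraw truncates the additive noise conditionally on the
  # linear predictor, which attenuates the raw OLS slope. The analytic
  # truncated-normal mean E[y|x] = lin + sigma * phi(lin/sigma)/Phi(lin/sigma)
  # provides the oracle expectation for the slope actually generated.
  x <- w$`2C9`
  lin <- 1.693 + 0.862 * x
  sigma <- sqrt(var(lin) * (1 - 0.235) / 0.235)
  ey <- lin + sigma * dnorm(lin / sigma) / pnorm(lin / sigma)
  slope_oracle <- coef(lm(ey ~ x))[[2]]
  expect_lt(abs(coef(fit)[[2]] - slope_oracle) / slope_oracle, 0.05)
  # and the attenuation itself is bounded: the slope stays within 10% of the
  # generative coefficient
  expect_lt(abs(coef(fit)[[2]] - 0.862) / 0.862, 0.10)
})

test_that("kinetic curve generation round-trips through the fitter", {
  clean <- generate_kinetic_curves(256.2, 219.2, cyp = "2C9", noise_cv = 0)
  expect_equal(clean$velocity_pmol_min_mg,
               256.2 * clean$substrate_conc_uM /
                 (219.2 + clean$substrate_conc_uM))
  fit <- mm_fit(clean$substrate_conc_uM, clean$velocity_pmol_min_mg)
  expect_lt(abs(fit$vmax - 256.2) / 256.2, 1e-4)
  expect_lt(abs(fit$km - 219.2) / 219.2, 1e-4)
  # the midazolam grid spans the printed endpoints with 8 points
  mdz <- generate_kinetic_curves(788, 1.9, cyp = "3A4/5", noise_cv = 0)
  expect_equal(nrow(mdz), 8L)
  expect_equal(min(mdz$substrate_conc_uM), 0.39)
  expect_equal(max(mdz$substrate_conc_uM), 50)
  expect_error(generate_kinetic_curves(1, 1, cyp = "9Z9"),
               class = "cypivive_config_error")
})

test_that("noisy curve fits are nearly unbiased for V_max over many seeds", {
  est <- purrr::map_dbl(1:100, function(seed) {
    curves <- generate_kinetic_curves(256.2, 219.2, cyp = "2C9",
                                      noise_cv = 0.05, seed = seed)
    mm_fit(curves$substrate_conc_uM, curves$velocity_pmol_min_mg)$vmax
  })
  expect_lt(abs(mean(est) - 256.2) / 256.2, 0.02)
})

test_that("curve noise is seed-deterministic and local to the call", {
  a <- generate_kinetic_curves(100, 10, "1A2", noise_cv = 0.05, seed = 99)
  b <- generate_kinetic_curves(100, 10, "1A2", noise_cv = 0.05, seed = 99)
  expect_identical(a, b)
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(generate_kinetic_curves(100, 10, "1A2", seed = 5))
    after <- runif(1)
  })
  expect_identical(before, after)
})
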
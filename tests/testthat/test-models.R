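test_that("published registry holds the eleven models with the right structure", {
  reg <- published_models()
  expect_s3_class(reg, "cyp_registry")
  expect_equal(nrow(reg), 11L)
  expect_equal(sum(reg$parameter == "vmax"), 5L)
  expect_equal(sum(reg$parameter == "km"), 1L)
  expect_equal(sum(reg$parameter == "clint"), 5L)
  preds <- unique(unlist(purrr::map(reg$model, ~ names(.x$terms))))
  expect_setequal(preds, c("1A2", "2B6", "2C9", "2C19"))
  expect_error(registry_get(reg, "1A2", "vmax"),
               class = "cypivive_config_error")
})

test_that("published fit statistics satisfy the F / adjusted-R2 identities", {
  reg <- published_models()
  for (m in reg$model) {
    ms <- model_stats(m$r2, m$n, length(m$terms))
    # published statistics come from unrounded R2; the registry prints R2 to
    # 3 decimals, which propagates to ~1.5% on F and ~0.0015 on adjusted R2
    expect_lt(abs(ms$f_stat - m$f_stat) / m$f_stat, 0.015)
    expect_lt(abs(ms$r2_adj - m$r2_adj), 0.0015)
  }
})

test_that("model_stats handles the boundary cases", {
  null_fit <- model_stats(0, 105, 1)
  expect_identical(null_fit$f_stat, 0)
  expect_equal(null_fit$r2_adj, -1 / 103)
  expect_identical(model_stats(1, 105, 1)$f_stat, Inf)
  expect_error(model_stats(0.5, 3, 2), class = "cypivive_input_error")
  expect_error(model_stats(-0.1, 105, 1), class = "cypivive_domain_error")
})

test_that("apply_model evaluates the linear predictor and flags negatives", {
  reg <- published_models()
  m <- registry_get(reg, "2D6", "vmax")
  expect_equal(apply_model(m, c("2C9" = 256.2)), 133.9302, tolerance = 1e-8)
  expect_equal(apply_model(m, c("2C9" = 0, "1A2" = 99)), m$intercept)
  expect_error(apply_model(m, c("1A2" = 1)), class = "cypivive_input_error")
  km_model <- registry_get(reg, "3A4/5", "km")
  expect_warning(out <- apply_model(km_model, c("1A2" = 1000)),
                 class = "cypivive_negative_prediction")
  expect_lt(out, 0) # unclamped
})

test_that("stepwise selection matches the exhaustive rule-following oracle", {
  for (seed in 1:12) {
    withr::with_seed(seed, {
      n <- 50
      X <- as.data.frame(matrix(rlnorm(n * 4, 0, 0.6), n,
                                dimnames = list(NULL, c("w", "x", "y", "z"))))
      beta <- sample(c(0, 0, 0.8, 0.5)) # random subset of true predictors
      resp <- 2 + as.matrix(X) %*% beta + rnorm(n, 0, 1)
      dat <- dplyr::bind_cols(tibble::tibble(resp = drop(resp)), X)
      fit <- stepwise_fit(dat, "resp", c("w", "x", "y", "z"))
      expect_identical(sort(names(fit$terms)),
                       oracle_stepwise(drop(resp), X))
    })
  }
})

test_that("stepwise recovers a planted single predictor with honest statistics", {
  withr::with_seed(11, {
    n <- 105
    x1 <- rlnorm(n, log(1.17), 0.62)
    lin <- 1.693 + 0.862 * x1
    sigma <- sqrt(var(lin) * (1 - 0.235) / 0.235)
    dat <- tibble::tibble(
      x1 = x1, x2 = rlnorm(n, 0, 0.5), x3 = rlnorm(n, 0, 0.5),
      resp = lin + rnorm(n, 0, sigma)
    )
    fit <- stepwise_fit(dat, "resp", c("x1", "x2", "x3"))
    expect_identical(names(fit$terms), "x1")
    # closed-form OLS oracle and its 95% CI on the generated sample
    Xm <- cbind(1, dat$x1)
    beta <- solve(crossprod(Xm), crossprod(Xm, dat$resp))
    se <- sqrt(diag(solve(crossprod(Xm))) *
                 sum((dat$resp - Xm %*% beta)^2) / (n - 2))
    expect_equal(unname(fit$terms[["x1"]]), beta[2], tolerance = 1e-8)
    tcrit <- qt(0.975, n - 2)
    expect_lt(abs(beta[2] - 0.862), tcrit * se[2])
    expect_lt(abs(fit$intercept - 1.693), tcrit * se[1])
    expect_equal(fit$r2, summary(lm(resp ~ x1, dat))$r.squared)
  })
})

test_that("pure-noise candidates yield an intercept-only model", {
  withr::with_seed(3, {
    dat <- tibble::tibble(resp = rnorm(105), a = rnorm(105), b = rnorm(105),
                          c = rnorm(105))
  })
  fit <- stepwise_fit(dat, "resp", c("a", "b", "c"))
  expect_length(fit$terms, 0)
  expect_equal(fit$r2, 0)
})

test_that("stepwise guards thresholds and data sufficiency", {
  dat <- tibble::tibble(resp = rnorm(3), a = rnorm(3), b = rnorm(3))
  expect_error(stepwise_fit(dat, "resp", c("a", "b")),
               class = "cypivive_insufficient_data")
  expect_error(stepwise_fit(dat, "resp", c("a"), p_enter = 0.1, p_remove = 0.05),
               class = "cypivive_config_error")
  expect_error(stepwise_fit(dat, "resp", c("resp", "a")),
               class = "cypivive_input_error")
})

test_that("derive_km is the ratio identity", {
  expect_equal(derive_km(344.4, 138.9), 2.479482, tolerance = 1e-6)
  expect_equal(derive_km(897.7, 507.5), 1.768867, tolerance = 1e-6)
  expect_identical(derive_km(10, 10), 1)
  expect_error(derive_km(10, 0), class = "cypivive_domain_error")
})

test_that("predict_cohort at the published medians reproduces the predicted medians", {
  med <- median_donor_activities()
  out <- predict_cohort(med)
  get <- function(cy, par) out$value[out$cyp == cy & out$parameter == par]
  expect_equal(get("2A6", "clint"), 138.8384, tolerance = 1e-6)
  expect_equal(get("2C8", "clint"), 2.70154, tolerance = 1e-6)
  expect_equal(get("2D6", "clint"), 4.43226, tolerance = 1e-6)
  expect_equal(get("2D6", "vmax"), 133.9302, tolerance = 1e-6)
  expect_equal(get("2E1", "vmax"), 581.789, tolerance = 1e-6)
  # K_m filled by the ratio identity, never the K_m regression
  expect_equal(get("2A6", "km"), get("2A6", "vmax") / get("2A6", "clint"))
  expect_setequal(unique(out$cyp), c("2A6", "2C8", "2D6", "2E1", "3A4/5"))
})

test_that("predict_cohort is empty on empty input and matches a scalar loop", {
  empty <- predict_cohort(median_donor_activities()[0, ])
  expect_equal(nrow(empty), 0L)

  cohort <- generate_cohort(12, seed = 5)
  measured <- dplyr::filter(cohort$activities,
                            cyp %in% c("1A2", "2B6", "2C9", "2C19"))
  out <- predict_cohort(measured)
  reg <- published_models()
  # scalar re-evaluation, one subject and response at a time
  for (sid in unique(measured$subject_id)[c(1, 5, 12)]) {
    for (cy in c("2A6", "3A4/5")) {
      for (par in c("vmax", "clint")) {
        m <- registry_get(reg, cy, par)
        val <- m$intercept
        for (p in names(m$terms)) {
          val <- val + m$terms[[p]] *
            measured$value[measured$subject_id == sid & measured$cyp == p &
                             measured$parameter == par]
        }
        got <- out$value[out$subject_id == sid & out$cyp == cy &
                           out$parameter == par]
        expect_equal(got, val, tolerance = 1e-10)
      }
    }
  }
})

test_that("median propagation holds exactly for positive-slope single-predictor models", {
  reg <- published_models()
  cohort <- generate_cohort(21, seed = 9) # odd cohort size
  measured <- dplyr::filter(cohort$activities,
                            cyp %in% c("1A2", "2B6", "2C9", "2C19"))
  out <- predict_cohort(measured, reg)
  single_pos <- purrr::keep(reg$model, ~ length(.x$terms) == 1 &&
                              .x$terms[[1]] > 0 && .x$parameter != "km")
  for (m in single_pos) {
    pred_cyp <- names(m$terms)
    med_in <- median(measured$value[measured$cyp == pred_cyp &
                                      measured$parameter == m$parameter])
    med_out <- median(out$value[out$cyp == m$cyp &
                                  out$parameter == m$parameter])
    expect_equal(med_out, apply_model(m, setNames(med_in, pred_cyp)),
                 tolerance = 1e-12)
  }
})

test_that("minimal predictor set is exact on the published registry and random instances", {
  reg <- published_models()
  expect_identical(minimal_predictor_set(reg[reg$parameter != "km", ]),
                   c("1A2", "2B6", "2C19", "2C9"))
  # a single response with a single one-predictor model
  solo <- list(r1 = list(cyp_model("2A6", "clint", 0, c("2C19" = 1))))
  expect_identical(minimal_predictor_set(solo), "2C19")

  cyps <- c("A", "B", "C", "D", "E", "F", "G", "H")
  for (seed in 1:8) {
    withr::with_seed(seed, {
      fams <- purrr::map(setNames(nm = paste0("resp", 1:6)), function(r) {
        purrr::map(1:5, function(i) {
          preds <- sample(cyps, sample(1:3, 1))
          cyp_model("2A6", "clint", 0, setNames(runif(length(preds)), preds))
        })
      })
      got <- minimal_predictor_set(fams)
      pred_sets <- purrr::map(fams, ~ purrr::map(.x, function(m) names(m$terms)))
      expect_length(got, oracle_min_cover_size(pred_sets))
      # and it actually covers every response
      expect_true(all(purrr::map_lgl(pred_sets, function(cands) {
        any(purrr::map_lgl(cands, ~ all(.x %in% got)))
      })))
    })
  }
})

test_that("prediction intervals centre at the mean, widen with leverage, and cover", {
  withr::with_seed(21, {
    n <- 80
    dat <- tibble::tibble(x1 = rnorm(n, 10, 2))
    dat$resp <- 5 + 2 * dat$x1 + rnorm(n, 0, 1.5)
  })
  fit <- stepwise_fit(dat, "resp", "x1")
  at_mean <- prediction_interval(fit, c(x1 = mean(dat$x1)))
  expect_equal(at_mean$fit - at_mean$low, at_mean$high - at_mean$fit)
  widths <- purrr::map_dbl(c(0, 1, 2, 4), function(d) {
    pi <- prediction_interval(fit, c(x1 = mean(dat$x1) + d))
    pi$high - pi$low
  })
  expect_true(all(diff(widths) > 0))
  # Monte-Carlo coverage of fresh observations at a fixed input. Conditional
  # on one training sample the true coverage is the normal mass the interval
  # captures, which the simulation must match; it must also sit near the
  # nominal 95%.
  withr::with_seed(22, {
    x0 <- 11
    fresh <- 5 + 2 * x0 + rnorm(10000, 0, 1.5)
    pi <- prediction_interval(fit, c(x1 = x0))
    cover <- mean(fresh >= pi$low & fresh <= pi$high)
    analytic <- pnorm(pi$high, 5 + 2 * x0, 1.5) - pnorm(pi$low, 5 + 2 * x0, 1.5)
    expect_lt(abs(cover - analytic), 0.01)
    expect_gt(cover, 0.92)
    expect_lt(cover, 0.98)
  })
  pub <- registry_get(published_models(), "2C8", "clint")
  expect_error(prediction_interval(pub, c("2C9" = 1)),
               class = "cypivive_unsupported")
})

test_that("registry round-trips through JSON losslessly", {
  reg <- published_models()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_model_registry(reg, tmp)
  back <- read_model_registry(tmp)
  expect_equal(nrow(back), nrow(reg))
  for (i in seq_len(nrow(reg))) {
    expect_identical(back$model[[i]]$terms, reg$model[[i]]$terms)
    expect_identical(back$model[[i]]$intercept, reg$model[[i]]$intercept)
  }
})
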
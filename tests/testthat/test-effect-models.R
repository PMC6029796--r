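# hand-built 2x2 monthly count table used by the closed-form checks
toy_counts <- function(beds = 1000) {
  data.frame(
    hospital = rep(rep(c("control", "intervention"), each = 2), 2),
    year = rep(c("pre", "post"), each = 4),
    month_index = rep(1:2, 4),
    n_presentations = c(50, 60, 40, 50, 55, 65, 30, 40),
    n_admissions = c(20, 25, 15, 20, 22, 28, 10, 15),
    exposure_beds = beds, stringsAsFactors = FALSE)
}

test_that("the saturated Poisson fit reproduces observed cell rates", {
  cnt <- toy_counts()
  m <- fit_rate_model(cnt, model_spec("ed_rate"))
  am <- adjusted_means(m, ci = FALSE)
  for (r in seq_len(nrow(am))) {
    sel <- cnt$hospital == am$hospital[r] & cnt$year == am$year[r]
    observed <- mean(cnt$n_presentations[sel])  # beds = 1000 => rate = count
    expect_equal(am$estimate[r], observed, tolerance = 1e-8)
  }
})

test_that("doubling the exposure halves fitted rates exactly", {
  m1 <- fit_rate_model(toy_counts(1000), model_spec("ed_rate"))
  m2 <- fit_rate_model(toy_counts(2000), model_spec("ed_rate"))
  keep <- c("hospitalintervention", "yearpost", "intervention")
  expect_equal(m1$coefficients[keep], m2$coefficients[keep],
               tolerance = 1e-10)
  expect_equal(m1$coefficients[["(Intercept)"]] - log(2),
               m2$coefficients[["(Intercept)"]], tolerance = 1e-10)
  a1 <- adjusted_means(m1, ci = FALSE)
  a2 <- adjusted_means(m2, ci = FALSE)
  expect_equal(a2$estimate, a1$estimate / 2, tolerance = 1e-10)
})

test_that("reported ratios are the exponentials of the coefficients", {
  m <- fit_rate_model(toy_counts(), model_spec("admission_rate"))
  expect_identical(m$ratios$estimate, exp(m$ratios$log_estimate))
  expect_true(all(m$ratios$conf_low <= m$ratios$estimate &
                    m$ratios$estimate <= m$ratios$conf_high))
})

test_that("null generating effects give a program ratio compatible with 1", {
  cfg <- generator_config(months_per_period = 12, beds_per_catchment = 1500,
                          intervention_rate_ratio = 1,
                          intervention_los_ratio = 1, seed = 404)
  cnt <- generate_monthly_counts(cfg)
  m <- fit_rate_model(cnt, model_spec("ed_rate"))
  row <- m$ratios[m$ratios$term == "intervention", ]
  expect_lte(row$conf_low, 1)
  expect_gte(row$conf_high, 1)
})

test_that("constant LOS data yield null effect coefficients", {
  eps <- generate_episodes(small_config())
  eps$ed_los_hours <- 5
  # zero dispersion makes the gamma likelihood degenerate (AIC warning)
  m <- suppressWarnings(
    fit_los_model(eps, model_spec("ed_los", covariates = character(0))))
  b <- m$coefficients
  expect_equal(unname(b[names(b) != "(Intercept)"]), c(0, 0, 0),
               tolerance = 1e-8)
  expect_equal(unname(b[["(Intercept)"]]), log(5), tolerance = 1e-8)
})

test_that("multiplying one cell's LOS multiplies its fitted ratio", {
  eps <- generate_episodes(small_config())
  m1 <- fit_los_model(eps, model_spec("ed_los", covariates = character(0)))
  trt <- eps$hospital == "intervention" & eps$year == "post"
  eps2 <- eps
  eps2$ed_los_hours[trt] <- eps2$ed_los_hours[trt] * 2
  m2 <- fit_los_model(eps2, model_spec("ed_los", covariates = character(0)))
  r1 <- m1$ratios$estimate[m1$ratios$term == "intervention"]
  r2 <- m2$ratios$estimate[m2$ratios$term == "intervention"]
  expect_equal(r2, 2 * r1, tolerance = 1e-8)
})

test_that("program LOS ratio is recovered on synthetic data", {
  cfg <- generator_config(beds_per_catchment = 5000, seed = 909)
  eps <- generate_episodes(cfg)
  m <- fit_los_model(eps, model_spec("ed_los"))
  row <- m$ratios[m$ratios$term == "intervention", ]
  expect_lte(row$conf_low, 0.53 * 1.15)
  expect_gte(row$conf_high, 0.53 * 0.85)
  expect_lt(abs(row$estimate - 0.53), 0.08)
})

test_that("adjusted means are invariant to covariate reference coding", {
  eps <- generate_episodes(small_config(
    covariate_los_effects = list(gender = c(male = 1.3),
                                 triage = c("ATS1-2" = 1.5))))
  m1 <- fit_los_model(eps, model_spec("ed_los"))
  eps2 <- eps
  eps2$gender <- relevel(eps2$gender, "female")
  eps2$diagnosis_group <- relevel(eps2$diagnosis_group, "other")
  m2 <- fit_los_model(eps2, model_spec("ed_los"))
  a1 <- adjusted_means(m1, ci = FALSE)
  a2 <- adjusted_means(m2, ci = FALSE)
  expect_equal(a1$estimate, a2$estimate, tolerance = 1e-6)
})

test_that("the with/without contrast obeys the log-link algebra", {
  eps <- generate_episodes(small_config())
  m <- fit_los_model(eps, model_spec("ed_los", covariates = character(0)))
  ct <- intervention_contrast(m, nsim = 500, seed = 1)
  b3 <- exp(m$coefficients[["intervention"]])
  w <- ct$without[["estimate"]]
  expect_equal(ct$with[["estimate"]], w * b3, tolerance = 1e-10)
  expect_equal(ct$difference[["estimate"]], w * (b3 - 1), tolerance = 1e-10)
  expect_equal(ct$difference[["estimate"]],
               ct$with[["estimate"]] - ct$without[["estimate"]])
  expect_identical(ct$p_value,
                   m$ratios$p_value[m$ratios$term == "intervention"])
  # the without estimate is the saturated no-program cell mean prediction
  trt <- eps$hospital == "intervention" & eps$year == "post"
  expect_equal(ct$with[["estimate"]], mean(eps$ed_los_hours[trt]),
               tolerance = 1e-6)
})

test_that("contrast intervals come from the coefficient covariance", {
  eps <- generate_episodes(small_config())
  m <- fit_los_model(eps, model_spec("ed_los"))
  ct1 <- intervention_contrast(m, nsim = 4000, seed = 2)
  ct2 <- intervention_contrast(m, nsim = 4000, seed = 2)
  expect_identical(ct1$difference, ct2$difference)
  expect_lt(ct1$difference[["conf_low"]], ct1$difference[["estimate"]])
  expect_gt(ct1$difference[["conf_high"]], ct1$difference[["estimate"]])
})

test_that("residual diagnostics describe a well-specified gamma fit", {
  cfg <- generator_config(beds_per_catchment = 2485, seed = 77)
  eps <- generate_episodes(cfg)
  m <- fit_los_model(eps, model_spec("ed_los"))
  d <- residual_diagnostics(m)
  n <- nrow(m$data)
  expect_gt(n, 1500)
  expect_identical(nrow(d$residuals), n)
  expect_identical(nrow(d$qq), n)
  expect_identical(sum(d$histogram$counts), n)
  # the log-link score equation centres the Pearson residuals exactly;
  # deviance residuals of skewed gamma data sit slightly left of zero
  expect_lt(abs(mean(residuals(m$fit, type = "pearson"))), 1e-8)
  expect_lt(abs(mean(d$residuals$std_deviance)), 0.35)
  expect_gt(d$fit_stats[["deviance_ratio"]], 0.7)
  expect_lt(d$fit_stats[["deviance_ratio"]], 1.3)
  expect_gt(d$fit_stats[["pearson_ratio"]], 0.7)
  expect_lt(d$fit_stats[["pearson_ratio"]], 1.3)
  expect_false(is.unsorted(d$qq$sample))
})

test_that("model inputs are validated", {
  cnt <- toy_counts()
  expect_error(fit_rate_model(cnt[cnt$hospital == "control", ]),
               "cell")
  cnt_bad <- cnt; cnt_bad$exposure_beds[2] <- 0
  expect_error(fit_rate_model(cnt_bad), "exposure")
  eps <- generate_episodes(small_config())
  eps$ed_los_hours[4] <- -1
  expect_error(fit_los_model(eps), "positive")
  expect_error(model_spec("ed_rate", covariates = "gender"),
               "no patient-level covariates")
  expect_error(model_spec("ed_los", covariates = "bogus"), "unknown")
})
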
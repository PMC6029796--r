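test_that("a fixed seed makes episodes, counts and extracts identical", {
  cfg <- small_config()
  e1 <- generate_episodes(cfg)
  e2 <- generate_episodes(cfg)
  expect_identical(e1, e2)
  c1 <- generate_monthly_counts(cfg)
  c2 <- generate_monthly_counts(cfg)
  expect_identical(c1, c2)
  # monthly counts are the aggregation of the same episode draw
  expect_identical(c1, aggregate_monthly_counts(e1, cfg$beds_per_catchment,
                                                cfg$months_per_period))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_extract(e1, f1); write_extract(e2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("monthly count means recover the configured rates", {
  cfg <- generator_config(months_per_period = 150, beds_per_catchment = 1000,
                          baseline_rates = c(presentations = 60,
                                             admissions = 30),
                          hospital_rate_ratio = 1, year_rate_ratio = 1,
                          intervention_rate_ratio = c(presentations = 0.53,
                                                      admissions = 0.53),
                          seed = 314)
  cnt <- generate_monthly_counts(cfg)
  ref <- cnt$hospital == "control"
  trt <- cnt$hospital == "intervention" & cnt$year == "post"
  m_ref <- mean(cnt$n_presentations[ref])
  m_trt <- mean(cnt$n_presentations[trt])
  # identity cells: 60 per 1,000 beds per month within 3 Poisson s.e.
  expect_lt(abs(m_ref - 60), 3 * sqrt(60 / sum(ref)))
  # program cell attenuated by the configured rate ratio
  expect_lt(abs(m_trt / m_ref - 0.53), 0.05)
  # the program leaves the intervention hospital's pre period untouched
  pre_int <- cnt$hospital == "intervention" & cnt$year == "pre"
  expect_lt(abs(mean(cnt$n_presentations[pre_int]) - 60),
            3 * sqrt(60 / sum(pre_int)))
})

test_that("episode LOS means recover the configured gamma cell means", {
  cfg <- generator_config(months_per_period = 50, beds_per_catchment = 1600,
                          baseline_rates = c(presentations = 60,
                                             admissions = 30),
                          hospital_rate_ratio = 1, year_rate_ratio = 1,
                          intervention_rate_ratio = 1,
                          baseline_los_means = c(ed = 13.0, inpatient = 80),
                          hospital_los_ratio = 1, year_los_ratio = 1,
                          intervention_los_ratio = c(ed = 0.53,
                                                     inpatient = 1),
                          seed = 2718)
  eps <- generate_episodes(cfg)
  trt <- eps$hospital == "intervention" & eps$year == "post"
  n_trt <- sum(trt)
  expect_gt(n_trt, 4000)
  target <- 13.0 * 0.53  # 6.89 h
  # shape 1 => sd equals the mean; 3-s.e. law-of-large-numbers band
  expect_lt(abs(mean(eps$ed_los_hours[trt]) - target),
            3 * target / sqrt(n_trt))
  ref <- eps$hospital == "control" & eps$year == "pre"
  expect_lt(abs(mean(eps$ed_los_hours[ref]) - 13.0),
            3 * 13.0 / sqrt(sum(ref)))
  expect_true(all(eps$ed_los_hours > 0))
  expect_true(all(is.na(eps$inpatient_los_hours) != eps$admitted))
})

test_that("a large gamma shape collapses the LOS noise", {
  cfg <- small_config(los_shape = 1e6)
  eps <- generate_episodes(cfg)
  cells <- cell_rates(cfg)
  ref <- eps$hospital == "control" & eps$year == "pre"
  expect_lt(sd(eps$ed_los_hours[ref]), 0.05)
  expect_lt(abs(mean(eps$ed_los_hours[ref]) -
                  cells$ed_los_mean[cells$hospital == "control" &
                                      cells$year == "pre"]), 0.05)
})

test_that("covariate frequencies match the configured marginals", {
  cfg <- generator_config(seed = 1001)
  eps <- generate_episodes(cfg)
  n <- nrow(eps)
  mix <- default_covariate_mix()
  for (nm in names(mix)) {
    for (lv in names(mix[[nm]])) {
      p <- mix[[nm]][[lv]]
      obs <- mean(eps[[nm]] == lv)
      expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
    }
  }
  # the documented headline marginal: 62.6% female
  expect_equal(unname(mix$gender[["female"]]), 0.626, tolerance = 1e-3)
})

test_that("admissions never exceed presentations", {
  for (seed in c(1, 2, 3)) {
    cnt <- generate_monthly_counts(small_config(seed = seed))
    expect_true(all(cnt$n_admissions <= cnt$n_presentations))
    expect_true(all(cnt$exposure_beds > 0))
  }
  expect_error(generator_config(
    baseline_rates = c(presentations = 20, admissions = 30)),
    "admission rate exceeds")
})

test_that("configuration validation rejects invalid settings", {
  expect_error(generator_config(months_per_period = 0), "months_per_period")
  expect_error(generator_config(beds_per_catchment = -5),
               "beds_per_catchment")
  expect_error(generator_config(baseline_los_means = c(ed = 0,
                                                       inpatient = 80)),
               "baseline_los_means")
  bad_mix <- default_covariate_mix()
  bad_mix$gender <- c(male = 0.6, female = 0.6)
  expect_error(generator_config(covariate_mix = bad_mix), "sum to 1")
})

test_that("covariate-LOS multipliers shift cell means multiplicatively", {
  eff <- list(triage = c("ATS1-2" = 2))
  cfg <- generator_config(months_per_period = 40, beds_per_catchment = 1500,
                          hospital_rate_ratio = 1, year_rate_ratio = 1,
                          intervention_rate_ratio = 1,
                          hospital_los_ratio = 1, year_los_ratio = 1,
                          intervention_los_ratio = 1,
                          baseline_los_means = c(ed = 10, inpatient = 80),
                          covariate_los_effects = eff, seed = 5)
  eps <- generate_episodes(cfg)
  hi <- eps$triage == "ATS1-2"
  ratio <- mean(eps$ed_los_hours[hi]) / mean(eps$ed_los_hours[!hi])
  expect_lt(abs(ratio - 2), 0.25)
})

test_that("CSV extracts round-trip losslessly", {
  eps <- generate_episodes(small_config())
  f <- tempfile(fileext = ".csv")
  write_extract(eps, f)
  back <- read_extract(f)
  expect_equal(back, eps, tolerance = 1e-12)
  cnt <- generate_monthly_counts(small_config())
  f2 <- tempfile(fileext = ".csv")
  write_extract(cnt, f2)
  back2 <- read_extract(f2)
  expect_equal(back2$n_presentations, cnt$n_presentations)
  expect_equal(as.character(back2$hospital), cnt$hospital)
  # header-only files read as empty typed frames
  f3 <- tempfile(fileext = ".csv")
  write_extract(eps[0, ], f3)
  empty <- read_extract(f3)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), names(eps))
  unlink(c(f, f2, f3))
})

test_that("malformed extracts are rejected with line numbers", {
  eps <- generate_episodes(small_config())
  f <- tempfile(fileext = ".csv")
  write_extract(eps, f)
  txt <- readLines(f)
  txt[3] <- sub("male|female", "unknown_gender", txt[3])
  writeLines(txt, f)
  expect_error(read_extract(f), "unknown_gender.*line.*3")
  write_extract(eps, f)
  txt <- readLines(f)
  flds <- strsplit(txt[5], ",")[[1]]
  flds[10] <- "-4.5"  # ed_los_hours
  txt[5] <- paste(flds, collapse = ",")
  writeLines(txt, f)
  expect_error(read_extract(f), "ed_los_hours.*line.*5")
  unlink(f)
})
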
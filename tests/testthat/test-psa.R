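params <- default_parameter_set()
specs <- default_distribution_specs()
psa_fix <- run_psa(params, specs, n_trials = 4000, seed = 11)

test_that("method-of-moments gamma reproduces the stated mean and s.e.", {
  spec <- dist_spec("c", "gamma_mom", baseline = 13.09, se = 1.06)
  set.seed(1)
  x <- sample_parameter(spec, 1e5)
  expect_lt(abs(mean(x) - 13.09), 3 * 1.06 / sqrt(1e5))
  expect_lt(abs(sd(x) - 1.06), 0.01)
  expect_true(all(x > 0))
})

test_that("triangular draws are symmetric about the baseline and bounded", {
  spec <- dist_spec("k", "triangular", lo = 0.75 * 193, mode = 193,
                    hi = 1.25 * 193)
  set.seed(2)
  x <- sample_parameter(spec, 1e5)
  tri_sd <- 0.25 * 193 / sqrt(6)
  expect_lt(abs(mean(x) - 193), 3 * tri_sd / sqrt(1e5))
  expect_true(all(x >= 0.75 * 193 & x <= 1.25 * 193))
})

test_that("fixed specs always return the baseline", {
  expect_identical(sample_parameter(dist_spec("j", "fixed", baseline = 2.485),
                                    50),
                   rep(2.485, 50))
})

test_that("invalid distribution specs are rejected", {
  expect_error(dist_spec("x", "uniform", lo = 2, hi = 1), "lo < hi")
  expect_error(dist_spec("x", "triangular", lo = 0, mode = 3, hi = 2),
               "mode")
  expect_error(dist_spec("x", "gamma_mom", baseline = 5), "se")
  expect_error(dist_spec("x", "normal", baseline = 5, se = -1), "se")
})

test_that("all-fixed specs collapse the PSA onto the deterministic cost", {
  fixed_specs <- lapply(specs, function(s) {
    base <- if (s$id %in% c("equipment_life", "discount_rate") ||
                is.null(s$baseline)) params[[s$id]] else s$baseline
    dist_spec(s$id, "fixed", baseline = base)
  })
  res <- run_psa(params, fixed_specs, n_trials = 100, seed = 3)
  expect_equal(res$summary$sd, 0)
  expect_equal(unique(res$draws), net_cost(params)$C)
})

test_that("identical seeds give identical PSA results", {
  a <- run_psa(params, specs, n_trials = 500, seed = 77)
  b <- run_psa(params, specs, n_trials = 500, seed = 77)
  expect_identical(a$draws, b$draws)
  expect_identical(a$inputs, b$inputs)
})

test_that("with no utilisation differences every draw is a pure cost", {
  p0 <- params
  p0$e <- p0$f <- p0$g <- p0$h <- 0
  vary <- Filter(function(s) !s$id %in% c("e", "f", "g", "h"), specs)
  res <- run_psa(p0, vary, n_trials = 1000, seed = 5)
  expect_true(all(res$draws >= 0))
  expect_equal(res$draws, res$breakdown$A)
})

test_that("scaling the ambulance unit cost scales its cost share exactly", {
  specs2 <- lapply(specs, function(s) {
    if (s$id == "m") dist_spec("m", "triangular", lo = 2 * s$lo,
                               mode = 2 * s$mode, hi = 2 * s$hi) else s
  })
  a <- run_psa(params, specs, n_trials = 1000, seed = 13)
  b <- run_psa(params, specs2, n_trials = 1000, seed = 13)
  expect_equal(b$breakdown$B3, 2 * a$breakdown$B3, tolerance = 1e-12)
})

test_that("variance contributions resolve the analytic toy cases", {
  set.seed(8)
  x1 <- rnorm(5000)
  x2 <- rnorm(5000)
  only <- variance_contributions(
    toy_psa_result(x1, cbind(x1 = x1, x2 = rep(1, 5000))))
  expect_equal(only$contribution[only$parameter == "x1"], 100)
  expect_equal(only$contribution[only$parameter == "x2"], 0)
  both <- variance_contributions(
    toy_psa_result(x1 + x2, cbind(x1 = x1, x2 = x2)))
  expect_true(all(both$contribution > 45 & both$contribution < 55))
  expect_equal(sum(both$contribution), 100)
  flipped <- variance_contributions(
    toy_psa_result(x1 - x2, cbind(x1 = x1, x2 = x2)))
  expect_lt(flipped$contribution[flipped$parameter == "x2"], -45)
})

test_that("contributions over the sampled parameters sum to 100%", {
  vc <- variance_contributions(psa_fix)
  expect_equal(sum(abs(vc$contribution)), 100, tolerance = 1e-8)
  expect_setequal(vc$parameter,
                  vapply(specs, function(s) s$id, character(1)))
})

test_that("draw summaries follow the documented conventions", {
  s <- summarize_draws(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$sd, sd(c(1, 2, 3, 4)))
  const <- summarize_draws(rep(7, 10), probs = c(0.1, 0.5, 0.9))
  expect_equal(const$sd, 0)
  expect_true(all(const$percentiles == 7))
  set.seed(4)
  z <- rnorm(1e5, 2, 3)
  s2 <- summarize_draws(z)
  expect_lt(abs(s2$percentiles[["97.5%"]] - (mean(z) + 1.96 * sd(z))), 0.1)
  expect_error(summarize_draws(numeric(0)), "non-empty")
})

test_that("percentiles bracket the median and the batching law holds", {
  s <- psa_fix$summary
  expect_lte(s$percentiles[["2.5%"]], s$median)
  expect_lte(s$median, s$percentiles[["97.5%"]])
  # MC convergence: sd of 200-draw batch means tracks sd/sqrt(200)
  bm <- colMeans(matrix(psa_fix$draws, nrow = 200))
  ratio <- sd(bm) / (s$sd / sqrt(200))
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 1.6)
})

test_that("a trial overflowing to non-finite cost aborts with context", {
  bad <- c(specs, list(dist_spec("e", "normal", baseline = 0, se = 1e308)))
  bad <- bad[!duplicated(vapply(bad, function(s) s$id, character(1)),
                         fromLast = TRUE)]
  expect_error(run_psa(params, bad, n_trials = 20, seed = 1),
               "non-finite")
})

test_that("the normal count sampler replaces the Poisson draws", {
  res <- run_psa(params, specs, n_trials = 2000, seed = 21,
                 count_sampler = "normal")
  a <- res$inputs[, "a"]
  expect_gt(sum(a != round(a)), 0)
  expect_lt(abs(sd(a) - 6.58), 0.5)
})
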
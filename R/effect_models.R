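los_confounders <- c("age_group", "gender", "triage", "diagnosis_group",
                     "attendance_day", "attendance_time")

#' Specification of a difference-in-differences GLM
#'
#' The four outcomes map onto two families: the monthly count rates use a
#' Poisson log-linear model with a `log(exposure_beds/1000)` offset (so
#' coefficients act on rates per 1,000 RACF beds per month), and the
#' episode-level lengths of stay use a gamma GLM with log link, adjusted by
#' default for the patient-level confounders (age group, gender, triage,
#' diagnosis group, attendance day and time). All models contain the
#' hospital and period main effects plus the program indicator, which in a
#' two-hospital two-period design equals their interaction.
#'
#' @param outcome one of `"ed_rate"`, `"admission_rate"`, `"ed_los"`,
#'   `"inpatient_los"`.
#' @param covariates character vector of confounder columns (LOS models
#'   only; rate models are fit at month level where patient covariates do
#'   not exist). Use `character(0)` for an unadjusted LOS model.
#' @return An object of class `hinh_model_spec` with fields `outcome`,
#'   `family` (`"poisson_log"` or `"gamma_log"`), `covariates`, `offset`.
#' @export
model_spec <- function(outcome = c("ed_rate", "admission_rate", "ed_los",
                                   "inpatient_los"),
                       covariates = NULL) {
  outcome <- match.arg(outcome)
  is_rate <- outcome %in% c("ed_rate", "admission_rate")
  if (is_rate) {
    if (!is.null(covariates) && length(covariates))
      stopf("rate models take no patient-level covariates")
    covariates <- character(0)
  } else {
    covariates <- covariates %||% los_confounders
    bad <- setdiff(covariates, los_confounders)
    if (length(bad)) stopf("unknown covariate(s): %s",
                           paste(bad, collapse = ", "))
  }
  structure(list(outcome = outcome,
                 family = if (is_rate) "poisson_log" else "gamma_log",
                 covariates = covariates, offset = is_rate),
            class = "hinh_model_spec")
}

design_columns <- function(data) {
  data$hospital <- factor(as.character(data$hospital), hospital_levels)
  data$year <- factor(as.character(data$year), year_levels)
  data$intervention <- as.integer(data$hospital == "intervention" &
                                    data$year == "post")
  data
}

new_effect_model <- function(fit, spec, data) {
  cs <- stats::coef(summary(fit))
  est <- cs[, 1]
  se <- cs[, 2]
  z <- stats::qnorm(0.975)
  ratios <- data.frame(term = rownames(cs), log_estimate = est,
                       se = se, estimate = exp(est),
                       conf_low = exp(est - z * se),
                       conf_high = exp(est + z * se),
                       p_value = cs[, 4], row.names = NULL,
                       stringsAsFactors = FALSE)
  df <- fit$df.residual
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  structure(list(fit = fit, spec = spec, data = data,
                 coefficients = stats::coef(fit), vcov = stats::vcov(fit),
                 ratios = ratios,
                 dispersion = summary(fit)$dispersion,
                 fit_stats = c(deviance_ratio = fit$deviance / df,
                               pearson_ratio = pearson / df,
                               df_residual = df)),
            class = "hinh_effect_model")
}

check_converged <- function(fit) {
  if (!fit$converged)
    stopf("GLM did not converge after %d IWLS iterations (deviance %.6g); %s",
          fit$iter, fit$deviance,
          "the design may be separated or a cell may be empty")
  fit
}

#' Fit a Poisson difference-in-differences rate model
#'
#' Maximum-likelihood Poisson log-linear fit of a monthly count outcome on
#' hospital, period and the program indicator, with `log(exposure/1000)`
#' offset so exponentiated coefficients are rate ratios per 1,000 RACF
#' beds per month.
#'
#' @param counts monthly-count data frame (see
#'   [generate_monthly_counts()]): needs `hospital`, `year`,
#'   `n_presentations` or `n_admissions`, `exposure_beds`.
#' @param spec a rate [model_spec()].
#' @return A `hinh_effect_model`: the `glm` fit plus the exponentiated
#'   coefficient table (`$ratios`, with 95% Wald CIs and p-values) and fit
#'   statistics (deviance/df, Pearson chi-square/df).
#' @export
fit_rate_model <- function(counts, spec = model_spec("ed_rate")) {
  stopifnot(inherits(spec, "hinh_model_spec"))
  if (spec$family != "poisson_log")
    stopf("fit_rate_model needs a rate outcome spec")
  ycol <- switch(spec$outcome, ed_rate = "n_presentations",
                 admission_rate = "n_admissions")
  need <- c("hospital", "year", ycol, "exposure_beds")
  if (!all(need %in% names(counts)))
    stopf("counts must contain columns: %s", paste(need, collapse = ", "))
  data <- design_columns(as.data.frame(counts))
  if (any(!is.finite(data$exposure_beds) | data$exposure_beds <= 0))
    stopf("exposure_beds must be strictly positive")
  cells <- table(data$hospital, data$year)
  if (any(cells == 0L))
    stopf("every hospital x period cell needs at least one observation")
  data$.y <- data[[ycol]]
  fit <- stats::glm(.y ~ hospital + year + intervention +
                      offset(log(exposure_beds / 1000)),
                    family = stats::poisson(link = "log"), data = data)
  new_effect_model(check_converged(fit), spec, data)
}

#' Fit a gamma log-link length-of-stay model
#'
#' Gamma GLM with log link for an episode-level LOS outcome on hospital,
#' period, the program indicator and the confounder set of the spec.
#' The gamma family accommodates the strictly positive, right-skewed LOS
#' distribution; the log link keeps predictions positive and makes
#' exponentiated coefficients multiplicative LOS ratios. The dispersion is
#' estimated by the Pearson method. Covariates observed at a single level
#' are dropped from the formula.
#'
#' @param episodes episode data frame (see [generate_episodes()]).
#' @param spec a LOS [model_spec()].
#' @return A `hinh_effect_model` (see [fit_rate_model()]).
#' @export
fit_los_model <- function(episodes, spec = model_spec("ed_los")) {
  stopifnot(inherits(spec, "hinh_model_spec"))
  if (spec$family != "gamma_log")
    stopf("fit_los_model needs a LOS outcome spec")
  ycol <- switch(spec$outcome, ed_los = "ed_los_hours",
                 inpatient_los = "inpatient_los_hours")
  need <- c("hospital", "year", ycol, spec$covariates)
  if (!all(need %in% names(episodes)))
    stopf("episodes must contain columns: %s", paste(need, collapse = ", "))
  data <- design_columns(as.data.frame(episodes))
  if (spec$outcome == "inpatient_los")
    data <- data[!is.na(data$inpatient_los_hours), , drop = FALSE]
  if (!nrow(data)) stopf("no observations with a %s outcome", ycol)
  if (any(!is.finite(data[[ycol]]) | data[[ycol]] <= 0))
    stopf("all %s values must be strictly positive", ycol)
  cells <- table(data$hospital, data$year)
  if (any(cells == 0L))
    stopf("every hospital x period cell needs at least one observation")
  covs <- spec$covariates
  for (nm in covs) data[[nm]] <- droplevels(factor(data[[nm]]))
  covs <- covs[vapply(covs, function(nm) nlevels(data[[nm]]) > 1L,
                      logical(1))]
  data$.y <- data[[ycol]]
  form <- stats::reformulate(c("hospital", "year", "intervention", covs),
                             response = ".y")
  fit <- stats::glm(form, family = stats::Gamma(link = "log"), data = data)
  new_effect_model(check_converged(fit), spec, data)
}

# linear predictors for the model data with the design cell overridden
cell_lp <- function(model, hospital, year, intervention = NULL) {
  data <- model$data
  data$hospital <- factor(hospital, hospital_levels)
  data$year <- factor(year, year_levels)
  data$intervention <- intervention %||%
    as.integer(hospital == "intervention" & year == "post")
  tt <- stats::delete.response(stats::terms(model$fit))
  # neutralize the offset for prediction: adjusted rates are per 1,000 beds
  if (!is.null(attr(tt, "offset"))) data$exposure_beds <- 1000
  mf <- stats::model.frame(tt, data, xlev = model$fit$xlevels)
  X <- stats::model.matrix(tt, mf, contrasts.arg = model$fit$contrasts)
  off <- stats::model.offset(mf) %||% 0
  list(X = X, offset = off)
}

# mean response per coefficient draw, chunked to bound memory
standardized_mean_draws <- function(lp, beta_draws, chunk = 500L) {
  n_draws <- nrow(beta_draws)
  out <- numeric(n_draws)
  for (start in seq(1L, n_draws, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_draws)
    eta <- lp$X %*% t(beta_draws[idx, , drop = FALSE]) + lp$offset
    out[idx] <- colMeans(exp(eta))
  }
  out
}

#' Marginally standardized adjusted means per design cell
#'
#' For every hospital x period cell, predicts each observation's outcome as
#' if it belonged to that cell (covariates kept at their observed values),
#' and averages the predictions on the response scale over the pooled
#' covariate distribution (marginal standardization). Rate-model means are
#' per 1,000 RACF beds per month. Confidence intervals come from
#' multivariate-normal draws of the coefficient vector.
#'
#' @param model a fitted `hinh_effect_model`.
#' @param cells data frame with `hospital` and `year` columns (defaults to
#'   the four design cells present in the data).
#' @param ci compute simulation CIs (set `FALSE` for point estimates only).
#' @param nsim number of coefficient draws for the CIs.
#' @param seed optional seed for the coefficient draws.
#' @return Data frame with `hospital`, `year`, `estimate` and (with
#'   `ci = TRUE`) `conf_low`, `conf_high` (2.5/97.5 percentiles).
#' @export
adjusted_means <- function(model, cells = NULL, ci = TRUE, nsim = 2000L,
                           seed = NULL) {
  stopifnot(inherits(model, "hinh_effect_model"))
  observed <- unique(model$data[c("hospital", "year")])
  if (is.null(cells)) {
    cells <- expand.grid(hospital = hospital_levels, year = year_levels,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(cells))) {
    hit <- observed$hospital == cells$hospital[r] &
      observed$year == cells$year[r]
    if (!any(hit))
      stopf("design cell %s/%s has no observations", cells$hospital[r],
            cells$year[r])
  }
  beta_draws <- NULL
  if (ci) beta_draws <- with_seed(seed,
    MASS::mvrnorm(nsim, model$coefficients, model$vcov))
  res <- lapply(seq_len(nrow(cells)), function(r) {
    lp <- cell_lp(model, cells$hospital[r], cells$year[r])
    est <- mean(exp(lp$X %*% model$coefficients + lp$offset))
    if (!ci) return(data.frame(hospital = cells$hospital[r],
                               year = cells$year[r], estimate = est,
                               stringsAsFactors = FALSE))
    draws <- standardized_mean_draws(lp, beta_draws)
    qs <- stats::quantile(draws, c(0.025, 0.975), type = 7, names = FALSE)
    data.frame(hospital = cells$hospital[r], year = cells$year[r],
               estimate = est, conf_low = qs[1], conf_high = qs[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' With/without-program contrast for the intervention-hospital post period
#'
#' Predicts the adjusted mean of the intervention hospital's post period
#' twice — once with the program indicator forced to 0 (the counterfactual
#' "without" estimate) and once at its observed value 1 — and reports both
#' together with their difference. Interval estimates use parametric
#' simulation from the estimated coefficient covariance; the p-value is the
#' Wald p-value of the program coefficient, whose exponential also links
#' the two estimates (`with = without * exp(beta3)`).
#'
#' @param model a fitted `hinh_effect_model` containing the program term.
#' @param nsim number of coefficient draws (default 10,000).
#' @param seed optional seed for the draws.
#' @return A `hinh_intervention_contrast`: list with `without`, `with` and
#'   `difference` (each `estimate`, `conf_low`, `conf_high`), `p_value`,
#'   `ratio` (exp of the program coefficient) and `outcome`.
#' @export
intervention_contrast <- function(model, nsim = 10000L, seed = NULL) {
  stopifnot(inherits(model, "hinh_effect_model"))
  if (!"intervention" %in% names(model$coefficients))
    stopf("model does not contain the program indicator")
  lp0 <- cell_lp(model, "intervention", "post", intervention = 0L)
  m0 <- mean(exp(lp0$X %*% model$coefficients + lp0$offset))
  b3 <- model$coefficients[["intervention"]]
  m1 <- m0 * exp(b3)
  beta_draws <- with_seed(seed,
    MASS::mvrnorm(nsim, model$coefficients, model$vcov))
  d0 <- standardized_mean_draws(lp0, beta_draws)
  d1 <- d0 * exp(beta_draws[, "intervention"])
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), type = 7,
                                    names = FALSE)
  ci0 <- qs(d0); ci1 <- qs(d1); cid <- qs(d1 - d0)
  p <- model$ratios$p_value[model$ratios$term == "intervention"]
  structure(list(
    outcome = model$spec$outcome,
    without = c(estimate = m0, conf_low = ci0[1], conf_high = ci0[2]),
    with = c(estimate = m1, conf_low = ci1[1], conf_high = ci1[2]),
    difference = c(estimate = m1 - m0, conf_low = cid[1],
                   conf_high = cid[2]),
    ratio = exp(b3), p_value = p, nsim = nsim),
    class = "hinh_intervention_contrast")
}

#' @export
print.hinh_intervention_contrast <- function(x, ...) {
  fmt <- function(v) sprintf("%.2f (%.2f, %.2f)", v["estimate"],
                             v["conf_low"], v["conf_high"])
  cat(sprintf("<%s> without %s | with %s | difference %s | p = %.4g\n",
              x$outcome, fmt(x$without), fmt(x$with), fmt(x$difference),
              x$p_value))
  invisible(x)
}

#' Residual diagnostics for a fitted effect model
#'
#' Bundles what a residual check of the GLM needs: standardized deviance
#' residuals against fitted values, histogram bins, normal Q-Q pairs
#' (theoretical quantiles from average ranks, so ties share a plotting
#' position) and the deviance/df and Pearson chi-square/df statistics,
#' which should sit near one for a well-specified model.
#'
#' @param model a fitted `hinh_effect_model`.
#' @param bins histogram break specification (passed to [graphics::hist()];
#'   default `"Sturges"`).
#' @return A `hinh_diagnostics` list: `residuals` (data frame `fitted`,
#'   `std_deviance`), `histogram` (`breaks`, `counts`), `qq` (data frame
#'   `theoretical`, `sample`), `fit_stats`.
#' @export
residual_diagnostics <- function(model, bins = "Sturges") {
  stopifnot(inherits(model, "hinh_effect_model"))
  r <- stats::rstandard(model$fit)
  h <- graphics::hist(r, breaks = bins, plot = FALSE)
  n <- length(r)
  rk <- rank(r, ties.method = "average")
  qq <- data.frame(theoretical = stats::qnorm((rk - 0.5) / n), sample = r)
  qq <- qq[order(qq$sample), ]
  rownames(qq) <- NULL
  structure(list(
    residuals = data.frame(fitted = stats::fitted(model$fit),
                           std_deviance = r),
    histogram = list(breaks = h$breaks, counts = h$counts),
    qq = qq,
    fit_stats = model$fit_stats), class = "hinh_diagnostics")
}

#' @export
print.hinh_effect_model <- function(x, ...) {
  cat(sprintf("<%s model: %s>\n", x$spec$family, x$spec$outcome))
  print(x$ratios[c("term", "estimate", "conf_low", "conf_high", "p_value")],
        digits = 3)
  cat(sprintf("deviance/df = %.3f, Pearson chi-sq/df = %.3f (df = %d)\n",
              x$fit_stats[["deviance_ratio"]],
              x$fit_stats[["pearson_ratio"]],
              as.integer(x$fit_stats[["df_residual"]])))
  invisible(x)
}
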
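#' Distribution assumption for one uncertain parameter
#'
#' Describes how one cost-model parameter is sampled in the probabilistic
#' sensitivity analysis. Supported kinds:
#'
#' * `"poisson"` — draw with mean `baseline` (used for the monthly count
#'   rates; a Poisson has no free variance, so any stored `se` is kept only
#'   for the optional normal sampler, see [run_psa()]);
#' * `"gamma_mom"` — gamma fitted by method of moments to mean `baseline`
#'   and standard error `se`: shape `(baseline/se)^2`, scale `se^2/baseline`;
#' * `"normal"` — mean `baseline`, sd `se` (untruncated, so sign flips are
#'   possible and intended for the difference parameters);
#' * `"uniform"` — on `[lo, hi]`;
#' * `"triangular"` — on `[lo, hi]` with mode `mode`;
#' * `"fixed"` — always `baseline`.
#'
#' @param id parameter identifier: a [parameter_set()] field name
#'   (`"a"`..`"m"`, `"equipment_life"`, `"discount_rate"`, or a program-cost
#'   item such as `"hinh_staff"`).
#' @param kind one of `"poisson"`, `"gamma_mom"`, `"normal"`, `"uniform"`,
#'   `"triangular"`, `"fixed"`.
#' @param baseline central estimate (required except for pure-range kinds).
#' @param se standard error (normal, gamma_mom; optional for poisson).
#' @param lo,hi range bounds (uniform, triangular).
#' @param mode mode of the triangular distribution.
#' @return An object of class `hinh_dist_spec`.
#' @export
dist_spec <- function(id, kind, baseline = NULL, se = NULL,
                      lo = NULL, hi = NULL, mode = NULL) {
  kind <- match.arg(kind, c("poisson", "gamma_mom", "normal",
                            "uniform", "triangular", "fixed"))
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stopf("'id' must be a single non-empty string")
  spec <- structure(list(id = id, kind = kind, baseline = baseline,
                         se = se, lo = lo, hi = hi, mode = mode),
                    class = "hinh_dist_spec")
  switch(kind,
    poisson = {
      check_number(spec$baseline, "baseline", lower = 0, strict_lower = TRUE,
                   allow_vector = FALSE)
      if (!is.null(se)) check_number(se, "se", lower = 0, strict_lower = TRUE,
                                     allow_vector = FALSE)
    },
    gamma_mom = {
      check_number(spec$baseline, "baseline", lower = 0, strict_lower = TRUE,
                   allow_vector = FALSE)
      check_number(spec$se, "se", lower = 0, strict_lower = TRUE,
                   allow_vector = FALSE)
    },
    normal = {
      check_number(spec$baseline, "baseline", allow_vector = FALSE)
      check_number(spec$se, "se", lower = 0, strict_lower = TRUE,
                   allow_vector = FALSE)
    },
    uniform = {
      check_number(spec$lo, "lo", allow_vector = FALSE)
      check_number(spec$hi, "hi", allow_vector = FALSE)
      if (spec$lo >= spec$hi) stopf("uniform spec needs lo < hi")
    },
    triangular = {
      check_number(spec$lo, "lo", allow_vector = FALSE)
      check_number(spec$hi, "hi", allow_vector = FALSE)
      check_number(spec$mode, "mode", allow_vector = FALSE)
      if (spec$lo >= spec$hi || spec$mode < spec$lo || spec$mode > spec$hi)
        stopf("triangular spec needs lo <= mode <= hi and lo < hi")
    },
    fixed = check_number(spec$baseline, "baseline", allow_vector = FALSE)
  )
  spec
}

#' Triangular random deviates
#'
#' Inverse-CDF sampler for the triangular distribution on `[lo, hi]` with
#' mode `mode`.
#' @param n number of draws.
#' @param lo,mode,hi distribution support and mode.
#' @return Numeric vector of length `n`.
#' @export
rtriangular <- function(n, lo, mode, hi) {
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

#' Sample values from a distribution assumption
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @return Numeric vector of length `n`, drawn from the ambient RNG stream.
#' @export
sample_parameter <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "hinh_dist_spec"))
  check_number(n, "n", lower = 1, allow_vector = FALSE)
  switch(spec$kind,
    poisson    = stats::rpois(n, spec$baseline),
    gamma_mom  = stats::rgamma(n, shape = (spec$baseline / spec$se)^2,
                               scale = spec$se^2 / spec$baseline),
    normal     = stats::rnorm(n, spec$baseline, spec$se),
    uniform    = stats::runif(n, spec$lo, spec$hi),
    triangular = rtriangular(n, spec$lo, spec$mode, spec$hi),
    fixed      = rep.int(spec$baseline, n)
  )
}

#' Monte Carlo probabilistic sensitivity analysis of the net cost
#'
#' Repeatedly samples every uncertain parameter from its distribution
#' assumption, re-evaluates the annual net-cost ledger for each draw, and
#' summarizes the resulting net-cost distribution. All parameters are
#' sampled mutually independently. The ledger is evaluated through the same
#' [net_cost()] arithmetic as the deterministic analysis, vectorized across
#' trials.
#'
#' @param params baseline [parameter_set()]; parameters without a spec stay
#'   at their baseline value in every trial.
#' @param specs list of [dist_spec()] (default: the packaged assumptions).
#' @param n_trials number of Monte Carlo trials.
#' @param seed optional integer seed; the previous RNG state is restored on
#'   exit, and a fixed seed makes the full result reproducible.
#' @param count_sampler `"poisson"` (default) draws the monthly count rates
#'   from a Poisson with mean at baseline; `"normal"` instead uses a normal
#'   with the spec's stored `se` (the tabled standard error describes the
#'   regression estimate, which a Poisson cannot encode).
#' @return A `hinh_psa_result`: list with `draws` (net costs, length
#'   `n_trials`), `inputs` (trials x parameters matrix of sampled values),
#'   `breakdown` (vectorized ledger), `summary` (see [summarize_draws()]),
#'   plus the call metadata.
#' @export
run_psa <- function(params, specs = default_distribution_specs(),
                    n_trials = 10000L, seed = NULL,
                    count_sampler = c("poisson", "normal")) {
  stopifnot(inherits(params, "hinh_parameter_set"))
  count_sampler <- match.arg(count_sampler)
  check_number(n_trials, "n_trials", lower = 1, allow_vector = FALSE)
  n_trials <- as.integer(n_trials)
  if (!length(specs)) stopf("'specs' must contain at least one dist_spec")
  ids <- vapply(specs, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate parameter ids in 'specs'")
  unknown <- setdiff(ids, names(params))
  if (length(unknown)) stopf("spec ids not in the parameter set: %s",
                             paste(unknown, collapse = ", "))

  inputs <- with_seed(seed, {
    cols <- lapply(specs, function(s) {
      if (count_sampler == "normal" && s$kind == "poisson") {
        if (is.null(s$se))
          stopf("normal count sampler needs an 'se' on spec '%s'", s$id)
        s <- dist_spec(s$id, "normal", baseline = s$baseline, se = s$se)
      }
      sample_parameter(s, n_trials)
    })
    matrix(unlist(cols), nrow = n_trials, dimnames = list(NULL, ids))
  })

  trial_params <- unclass(params)
  for (id in ids) trial_params[[id]] <- inputs[, id]
  bd <- net_cost(structure(trial_params, class = "hinh_parameter_set"))
  draws <- bd$C
  if (!all(is.finite(draws))) {
    bad <- which(!is.finite(draws))[1L]
    stopf("trial %d produced a non-finite net cost; sampled inputs: %s",
          bad, paste(sprintf("%s=%.6g", ids, inputs[bad, ]), collapse = ", "))
  }
  structure(list(draws = draws, inputs = inputs, breakdown = bd,
                 summary = summarize_draws(draws), specs = specs,
                 params = params, n_trials = n_trials, seed = seed,
                 count_sampler = count_sampler),
            class = "hinh_psa_result")
}

#' Summary statistics of simulated net-cost draws
#'
#' @param draws numeric vector of simulated values.
#' @param probs percentile levels to report (default 2.5% and 97.5%).
#' @return List with `n`, `mean`, `median`, `sd` (n-1 denominator), `min`,
#'   `max` and the requested `percentiles` (linear interpolation between
#'   order statistics, i.e. [stats::quantile()] type 7).
#' @export
summarize_draws <- function(draws, probs = c(0.025, 0.975)) {
  if (!is.numeric(draws) || length(draws) == 0L)
    stopf("'draws' must be a non-empty numeric vector")
  check_number(probs, "probs", lower = 0, upper = 1)
  list(n = length(draws),
       mean = mean(draws),
       median = stats::median(draws),
       sd = stats::sd(draws),
       min = min(draws),
       max = max(draws),
       percentiles = stats::quantile(draws, probs, type = 7, names = TRUE))
}

#' Contribution of each sampled parameter to the net-cost variance
#'
#' Attributes the spread of the simulated net costs to the sampled inputs
#' with the signed squared rank-correlation convention common in
#' spreadsheet risk-analysis tools: for input `i`,
#' `contribution_i = sign(rho_i) * rho_i^2 / sum_j rho_j^2 * 100`, where
#' `rho_i` is the Spearman rank correlation between the input draws and the
#' net-cost draws. Constant inputs get a contribution of zero.
#'
#' @param result a `hinh_psa_result` from [run_psa()].
#' @return Data frame with columns `parameter`, `rho`, `contribution`
#'   (signed percentages summing to 100 over varied inputs), sorted by
#'   absolute contribution.
#' @export
variance_contributions <- function(result) {
  stopifnot(inherits(result, "hinh_psa_result"))
  inputs <- result$inputs
  draws <- result$draws
  rho <- vapply(colnames(inputs), function(id) {
    x <- inputs[, id]
    if (stats::sd(x) == 0) return(0)
    stats::cor(x, draws, method = "spearman")
  }, numeric(1))
  denom <- sum(rho^2)
  contribution <- if (denom > 0) sign(rho) * rho^2 / denom * 100 else rho * 0
  out <- data.frame(parameter = colnames(inputs), rho = rho,
                    contribution = contribution, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$contribution)), , drop = FALSE]
}

#' @export
print.hinh_psa_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<PSA: %d trials, %d sampled parameters%s>\n",
              x$n_trials, ncol(x$inputs),
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  cat(sprintf("  net cost: mean %s, median %s, sd %s\n",
              format_aud(s$mean), format_aud(s$median), format_aud(s$sd)))
  cat(sprintf("  range [%s, %s]; percentiles: %s\n",
              format_aud(s$min), format_aud(s$max),
              paste(sprintf("%s: %s", names(s$percentiles),
                            format_aud(s$percentiles)), collapse = ", ")))
  invisible(x)
}
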
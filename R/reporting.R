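#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs: which stages to execute,
#' where the parameter configuration and (optionally) pre-existing extracts
#' live, the generator settings, the PSA size and the master seed. The seed
#' drives every random stage (data generation, contrast simulation, PSA)
#' and is recorded in the output manifest.
#'
#' @param out_dir output directory (created if missing).
#' @param stages subset of `c("generate", "estimate", "cost", "psa")` in
#'   pipeline order. `estimate` needs extracts (from `generate` or from
#'   `episodes_path`/`counts_path`); `cost` uses the estimated differences
#'   when `estimate` ran, otherwise the parameter file's baselines.
#' @param params_path JSON parameter configuration (default: packaged).
#' @param generator a [generator_config()] for the `generate` stage.
#' @param episodes_path,counts_path optional CSV extracts to use when
#'   `generate` is not among the stages.
#' @param n_trials PSA trials.
#' @param seed master integer seed.
#' @return An object of class `hinh_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("generate", "estimate", "cost",
                                       "psa"),
                            params_path = system.file(
                              "extdata", "hinh_parameters.json",
                              package = "hinhcost"),
                            generator = generator_config(),
                            episodes_path = NULL, counts_path = NULL,
                            n_trials = 10000L, seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!file.exists(params_path))
    stopf("parameter config not found: %s", params_path)
  if (!"generate" %in% stages && "estimate" %in% stages) {
    if (is.null(episodes_path) || is.null(counts_path) ||
        !file.exists(episodes_path) || !file.exists(counts_path))
      stopf("the estimate stage needs existing extracts when 'generate' is skipped")
  }
  check_number(seed, "seed", allow_vector = FALSE)
  check_number(n_trials, "n_trials", lower = 1, allow_vector = FALSE)
  structure(list(out_dir = out_dir, stages = stages,
                 params_path = params_path, generator = generator,
                 episodes_path = episodes_path, counts_path = counts_path,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "hinh_pipeline_config")
}

ledger_rows <- function(bd, params = NULL) {
  items <- if (is.null(params)) NULL else data.frame(
    item = c("HiNH staff (including on-costs)",
             "Time in kind from other health professionals",
             "Staff travel", "Administration and training",
             "Stationery and office supplies", "Telephone communications",
             "Equipment (annualized)", "Office space"),
    amount = c(params$hinh_staff, params$in_kind, params$travel,
               params$admin_training, params$stationery, params$telephone,
               annualize_equipment(params$equipment_price,
                                   params$equipment_life,
                                   params$discount_rate),
               params$office_space),
    stringsAsFactors = FALSE)
  subtotals <- data.frame(
    item = c("A1: program staffing costs", "A2: program non-staff costs",
             "A: subtotal, program costs",
             "B1a: avoided ED presentation bed-hours",
             "B1b: shortened ED presentation bed-hours",
             "B1: differences in ED care utilisation",
             "B2a: avoided inpatient admission bed-hours",
             "B2b: shortened inpatient admission bed-hours",
             "B2: differences in inpatient care utilisation",
             "B3: differences in ambulance service utilisation",
             "B: subtotal, utilisation cost differences",
             "C: total net costs"),
    amount = c(bd$A1, bd$A2, bd$A, bd$B1a, bd$B1b, bd$B1, bd$B2a, bd$B2b,
               bd$B2, bd$B3, bd$B, bd$C),
    stringsAsFactors = FALSE)
  rbind(items, subtotals)
}

#' Render the annual net-cost ledger as text
#'
#' Formats a [net_cost()] breakdown in ledger order (program cost items,
#' A-subtotals, B-components, net cost) with whole-dollar rounding;
#' negative amounts (savings) carry a leading minus sign.
#'
#' @param bd a `hinh_cost_breakdown` (scalar, not vectorized).
#' @param params the [parameter_set()] behind the breakdown; when supplied,
#'   the individual program-cost items are listed too.
#' @return Character vector of report lines.
#' @export
render_cost_ledger <- function(bd, params = NULL) {
  stopifnot(inherits(bd, "hinh_cost_breakdown"))
  if (length(bd$C) != 1L)
    stopf("render_cost_ledger needs a scalar breakdown")
  rows <- ledger_rows(bd, params)
  width <- max(nchar(rows$item))
  c("Annual net costs of the HiNH program (AU$, negative = saving)",
    strrep("-", width + 16L),
    sprintf("%-*s %15s", width, rows$item, format_aud(rows$amount)))
}

#' Write the net-cost ledger to text and CSV files
#'
#' The CSV holds the unrounded in-memory amounts (column `amount`) next to
#' the rounded whole-dollar display value (`amount_display`), so re-parsing
#' recovers the exact figures.
#'
#' @param bd a scalar `hinh_cost_breakdown`.
#' @param txt_path,csv_path output paths (`NULL` to skip one of them).
#' @param params optional [parameter_set()] for the item rows.
#' @return Invisibly, the ledger rows data frame.
#' @export
write_cost_ledger <- function(bd, txt_path = NULL, csv_path = NULL,
                              params = NULL) {
  rows <- ledger_rows(bd, params)
  rows$amount_display <- format_aud(rows$amount)
  if (!is.null(txt_path))
    writeLines(render_cost_ledger(bd, params), txt_path)
  if (!is.null(csv_path))
    utils::write.csv(rows, csv_path, row.names = FALSE)
  invisible(rows)
}

#' Replace utilisation parameters with fitted model estimates
#'
#' Maps the four with/without-program contrasts onto the cost model's
#' utilisation parameters: the counterfactual without-program estimates
#' become `a`--`d` and the program-associated differences become `e`--`h`.
#'
#' @param params a [parameter_set()].
#' @param contrasts named list of [intervention_contrast()] results with
#'   elements `ed_rate`, `admission_rate`, `ed_los`, `inpatient_los`.
#' @return The updated `hinh_parameter_set`.
#' @export
update_parameter_set <- function(params, contrasts) {
  stopifnot(inherits(params, "hinh_parameter_set"))
  need <- c("ed_rate", "admission_rate", "ed_los", "inpatient_los")
  if (!all(need %in% names(contrasts)))
    stopf("contrasts must contain: %s", paste(need, collapse = ", "))
  slots <- list(ed_rate = c("a", "e"), admission_rate = c("b", "f"),
                ed_los = c("c", "g"), inpatient_los = c("d", "h"))
  for (nm in need) {
    ct <- contrasts[[nm]]
    stopifnot(inherits(ct, "hinh_intervention_contrast"))
    params[[slots[[nm]][1]]] <- unname(ct$without[["estimate"]])
    params[[slots[[nm]][2]]] <- unname(ct$difference[["estimate"]])
  }
  validate_parameter_set(params)
  params
}

#' Re-centre distribution assumptions on fitted model estimates
#'
#' After the estimation stage, the utilisation parameters `a`--`h` come
#' from the fitted models rather than the configuration file. This helper
#' re-centres their distribution assumptions accordingly: baselines move to
#' the fitted without-program estimates (`a`--`d`) and differences
#' (`e`--`h`), and standard errors are recovered from the simulation CI
#' widths (`(high - low) / (2 * 1.96)`). Other specs are untouched.
#'
#' @param specs list of [dist_spec()].
#' @param contrasts named list of [intervention_contrast()] results
#'   (`ed_rate`, `admission_rate`, `ed_los`, `inpatient_los`).
#' @return The updated spec list.
#' @export
update_distribution_specs <- function(specs, contrasts) {
  slots <- list(ed_rate = c("a", "e"), admission_rate = c("b", "f"),
                ed_los = c("c", "g"), inpatient_los = c("d", "h"))
  centre <- list()
  for (nm in names(slots)) {
    ct <- contrasts[[nm]]
    stopifnot(inherits(ct, "hinh_intervention_contrast"))
    wse <- (ct$without[["conf_high"]] - ct$without[["conf_low"]]) /
      (2 * stats::qnorm(0.975))
    dse <- (ct$difference[["conf_high"]] - ct$difference[["conf_low"]]) /
      (2 * stats::qnorm(0.975))
    centre[[slots[[nm]][1]]] <- c(ct$without[["estimate"]], wse)
    centre[[slots[[nm]][2]]] <- c(ct$difference[["estimate"]], dse)
  }
  lapply(specs, function(s) {
    if (!s$id %in% names(centre)) return(s)
    v <- centre[[s$id]]
    dist_spec(s$id, s$kind, baseline = v[1],
              se = if (s$kind == "fixed") NULL else v[2],
              lo = s$lo, hi = s$hi, mode = s$mode)
  })
}

effect_report <- function(models, contrasts, means) {
  list(
    ratios = lapply(models, function(m)
      m$ratios[c("term", "estimate", "conf_low", "conf_high", "p_value")]),
    fit_statistics = lapply(models, function(m) as.list(m$fit_stats)),
    adjusted_means = means,
    contrasts = lapply(contrasts, function(ct)
      list(without = as.list(ct$without), with = as.list(ct$with),
           difference = as.list(ct$difference), ratio = ct$ratio,
           p_value = ct$p_value)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate -> estimate -> cost -> PSA and writes
#' publication-style artifacts into `config$out_dir`:
#' `episodes.csv` / `monthly_counts.csv` (extracts), `effect_report.json`
#' (coefficient ratio tables, adjusted means, with/without contrasts),
#' `residual_diagnostics.csv`, `cost_ledger.txt` / `cost_ledger.csv`,
#' `psa_summary.json`, `psa_draws.csv`, `psa_contributions.csv`, and a
#' `manifest.json` recording the seed, stage list, parameter-file digest
#' and package version. Identical configurations (including seed) produce
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`episodes`,
#'   `counts`, `models`, `contrasts`, `params`, `breakdown`, `psa`,
#'   `manifest`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "hinh_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  result <- list()
  cfg_file <- read_parameter_config(config$params_path)
  params <- cfg_file$params

  if ("generate" %in% config$stages) {
    gen <- config$generator
    gen$seed <- gen$seed %||% config$seed
    episodes <- generate_episodes(gen)
    counts <- aggregate_monthly_counts(episodes, gen$beds_per_catchment,
                                       gen$months_per_period)
    write_extract(episodes, path("episodes.csv"))
    write_extract(counts, path("monthly_counts.csv"))
    files <- c(files, "episodes.csv", "monthly_counts.csv")
    result$episodes <- episodes
    result$counts <- counts
  } else if ("estimate" %in% config$stages) {
    result$episodes <- read_extract(config$episodes_path, "episodes")
    result$counts <- read_extract(config$counts_path, "monthly_counts")
  }

  if ("estimate" %in% config$stages) {
    models <- list(
      ed_rate = fit_rate_model(result$counts, model_spec("ed_rate")),
      admission_rate = fit_rate_model(result$counts,
                                      model_spec("admission_rate")),
      ed_los = fit_los_model(result$episodes, model_spec("ed_los")),
      inpatient_los = fit_los_model(result$episodes,
                                    model_spec("inpatient_los")))
    contrasts <- lapply(models, intervention_contrast,
                        seed = config$seed)
    means <- lapply(models, adjusted_means, seed = config$seed)
    jsonlite::write_json(effect_report(models, contrasts, means),
                         path("effect_report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    diag <- residual_diagnostics(models$ed_los)
    utils::write.csv(diag$residuals, path("residual_diagnostics.csv"),
                     row.names = FALSE)
    files <- c(files, "effect_report.json", "residual_diagnostics.csv")
    result$models <- models
    result$contrasts <- contrasts
    params <- update_parameter_set(params, contrasts)
    cfg_file$specs <- update_distribution_specs(cfg_file$specs, contrasts)
  }

  if ("cost" %in% config$stages) {
    bd <- net_cost(params)
    write_cost_ledger(bd, path("cost_ledger.txt"), path("cost_ledger.csv"),
                      params = params)
    files <- c(files, "cost_ledger.txt", "cost_ledger.csv")
    result$breakdown <- bd
  }

  if ("psa" %in% config$stages) {
    psa <- run_psa(params, cfg_file$specs, n_trials = config$n_trials,
                   seed = config$seed)
    contrib <- variance_contributions(psa)
    jsonlite::write_json(c(psa$summary,
                           list(share_negative = mean(psa$draws < 0))),
                         path("psa_summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    utils::write.csv(data.frame(trial = seq_along(psa$draws),
                                net_cost = psa$draws),
                     path("psa_draws.csv"), row.names = FALSE)
    utils::write.csv(contrib, path("psa_contributions.csv"),
                     row.names = FALSE)
    files <- c(files, "psa_summary.json", "psa_draws.csv",
               "psa_contributions.csv")
    result$psa <- psa
    result$contributions <- contrib
  }

  manifest <- list(
    package = "hinhcost",
    version = as.character(utils::packageVersion("hinhcost")),
    seed = config$seed, stages = config$stages,
    n_trials = config$n_trials,
    params_digest = unname(tools::md5sum(config$params_path)),
    files = files)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  result$manifest <- manifest
  result$params <- params
  result$files <- vapply(c(files, "manifest.json"), path, character(1))
  invisible(result)
}
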
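hospital_levels <- c("control", "intervention")
year_levels <- c("pre", "post")

episode_levels <- list(
  age_group = c("<65", "65-74", "75-84", "85-94", ">=95"),
  gender = c("male", "female"),
  triage = c("ATS1-2", "ATS3-5"),
  diagnosis_group = c("injury_poisoning", "respiratory", "circulatory",
                      "digestive", "genitourinary", "musculoskeletal_skin",
                      "mental_neurological", "other"),
  attendance_day = c("weekday", "weekend"),
  attendance_time = c("working_hours", "after_hours"))

#' Default covariate marginal distribution
#'
#' Marginal probabilities for the episode covariates, taken as exact count
#' fractions of a 449-episode RACF emergency-presentation cohort, e.g.
#' 62.6% female, 82.2% low-acuity triage, mostly weekday working-hours
#' arrivals.
#'
#' @return Named list of named probability vectors (each summing to 1)
#'   for `age_group`, `gender`, `triage`, `diagnosis_group`,
#'   `attendance_day`, `attendance_time`.
#' @export
default_covariate_mix <- function() {
  list(
    age_group = stats::setNames(c(29, 58, 137, 193, 32) / 449,
                                episode_levels$age_group),
    gender = stats::setNames(c(168, 281) / 449, episode_levels$gender),
    triage = stats::setNames(c(80, 369) / 449, episode_levels$triage),
    diagnosis_group = stats::setNames(
      c(104, 51, 42, 40, 22, 38, 23, 129) / 449,
      episode_levels$diagnosis_group),
    attendance_day = stats::setNames(c(339, 110) / 449,
                                     episode_levels$attendance_day),
    attendance_time = stats::setNames(c(284, 165) / 449,
                                      episode_levels$attendance_time))
}

# expand a scalar or named pair to the named length-2 convention
pair <- function(x, names, what) {
  if (length(x) == 1L) x <- rep_len(x, 2L)
  if (length(x) != 2L) stopf("'%s' must have length 1 or 2", what)
  if (is.null(names(x))) names(x) <- names else x <- x[names]
  if (anyNA(x)) stopf("'%s' must be named %s", what,
                      paste(names, collapse = "/"))
  x
}

#' Configuration of the synthetic utilisation-data generator
#'
#' Defines the study conditions emulated by [generate_episodes()] and
#' [generate_monthly_counts()]: a 2x2 pre-post controlled design (control /
#' intervention hospital, pre / post period) observed for
#' `months_per_period` months per cell over a catchment of
#' `beds_per_catchment` RACF beds. Monthly presentation and admission
#' counts are Poisson with cell means given by the baseline rates (per
#' 1,000 beds per month, reference cell = control hospital, pre period)
#' scaled by multiplicative hospital / period / program effects; lengths of
#' stay are gamma with multiplicative cell means and fixed shape. The
#' program effect applies only to the intervention-hospital post-period
#' cell, i.e. the intervention indicator equals the hospital-by-period
#' interaction.
#'
#' Rate arguments take a named pair `c(presentations = , admissions = )`
#' and LOS arguments a named pair `c(ed = , inpatient = )`; a scalar is
#' recycled to both. Defaults are calibrated to the fitted models of the
#' motivating study (e.g. program rate ratios 0.83 and 0.53, LOS ratios
#' 0.53 and 0.81).
#'
#' @param months_per_period observation months per period (default 3).
#' @param beds_per_catchment RACF beds per hospital catchment (exposure).
#' @param baseline_rates reference-cell ED presentation and admission rates
#'   per 1,000 beds per month.
#' @param hospital_rate_ratio,year_rate_ratio,intervention_rate_ratio
#'   multiplicative effects on the rates.
#' @param baseline_los_means reference-cell mean ED and inpatient LOS, hours.
#' @param hospital_los_ratio,year_los_ratio,intervention_los_ratio
#'   multiplicative effects on the LOS means.
#' @param los_shape gamma shape of the LOS noise (default 1, i.e.
#'   coefficient of variation 1: positive and highly right-skewed).
#' @param covariate_mix marginal covariate probabilities, see
#'   [default_covariate_mix()]. Covariates are sampled independently.
#' @param covariate_los_effects optional dependence hook: a named list
#'   (by covariate) of named multipliers (by level) applied to both LOS
#'   means, making covariate adjustment non-trivial. Off (`NULL`) by
#'   default.
#' @param seed optional integer seed stored in the config; when set, the
#'   generator output is fully reproducible.
#' @return An object of class `hinh_generator_config`.
#' @export
generator_config <- function(months_per_period = 3L,
                             beds_per_catchment = 2485,
                             baseline_rates = c(presentations = 74.92,
                                                admissions = 34.38),
                             hospital_rate_ratio = c(presentations = 0.94,
                                                     admissions = 1.17),
                             year_rate_ratio = c(presentations = 0.90,
                                                 admissions = 1.24),
                             intervention_rate_ratio = c(presentations = 0.83,
                                                         admissions = 0.53),
                             baseline_los_means = c(ed = 4.19,
                                                    inpatient = 86.24),
                             hospital_los_ratio = c(ed = 1.37,
                                                    inpatient = 1.10),
                             year_los_ratio = c(ed = 2.28, inpatient = 0.85),
                             intervention_los_ratio = c(ed = 0.53,
                                                        inpatient = 0.81),
                             los_shape = c(ed = 1, inpatient = 1),
                             covariate_mix = default_covariate_mix(),
                             covariate_los_effects = NULL,
                             seed = NULL) {
  rate_names <- c("presentations", "admissions")
  los_names <- c("ed", "inpatient")
  cfg <- structure(list(
    months_per_period = months_per_period,
    beds_per_catchment = beds_per_catchment,
    baseline_rates = pair(baseline_rates, rate_names, "baseline_rates"),
    hospital_rate_ratio = pair(hospital_rate_ratio, rate_names,
                               "hospital_rate_ratio"),
    year_rate_ratio = pair(year_rate_ratio, rate_names, "year_rate_ratio"),
    intervention_rate_ratio = pair(intervention_rate_ratio, rate_names,
                                   "intervention_rate_ratio"),
    baseline_los_means = pair(baseline_los_means, los_names,
                              "baseline_los_means"),
    hospital_los_ratio = pair(hospital_los_ratio, los_names,
                              "hospital_los_ratio"),
    year_los_ratio = pair(year_los_ratio, los_names, "year_los_ratio"),
    intervention_los_ratio = pair(intervention_los_ratio, los_names,
                                  "intervention_los_ratio"),
    los_shape = pair(los_shape, los_names, "los_shape"),
    covariate_mix = covariate_mix,
    covariate_los_effects = covariate_los_effects,
    seed = seed), class = "hinh_generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  check_number(cfg$months_per_period, "months_per_period", lower = 1,
               allow_vector = FALSE)
  check_number(cfg$beds_per_catchment, "beds_per_catchment", lower = 0,
               strict_lower = TRUE, allow_vector = FALSE)
  for (nm in c("baseline_rates", "hospital_rate_ratio", "year_rate_ratio",
               "intervention_rate_ratio", "baseline_los_means",
               "hospital_los_ratio", "year_los_ratio",
               "intervention_los_ratio", "los_shape"))
    check_number(cfg[[nm]], nm, lower = 0, strict_lower = TRUE)
  if (!is.list(cfg$covariate_mix) ||
      !all(names(episode_levels) %in% names(cfg$covariate_mix)))
    stopf("covariate_mix must provide probabilities for: %s",
          paste(names(episode_levels), collapse = ", "))
  for (nm in names(episode_levels)) {
    p <- cfg$covariate_mix[[nm]]
    check_number(p, nm, lower = 0, upper = 1)
    if (!setequal(names(p), episode_levels[[nm]]))
      stopf("covariate_mix$%s must be named with levels: %s", nm,
            paste(episode_levels[[nm]], collapse = ", "))
    if (abs(sum(p) - 1) > 1e-8)
      stopf("covariate_mix$%s must sum to 1 (got %.10f)", nm, sum(p))
  }
  rates <- cell_rates(cfg)
  if (any(rates$admission_rate > rates$presentation_rate))
    stopf(paste("configured admission rate exceeds presentation rate in the",
                "%s/%s cell"),
          rates$hospital[rates$admission_rate > rates$presentation_rate][1L],
          rates$year[rates$admission_rate > rates$presentation_rate][1L])
  if (!is.null(cfg$covariate_los_effects)) {
    eff <- cfg$covariate_los_effects
    if (!is.list(eff) || is.null(names(eff)) ||
        !all(names(eff) %in% names(episode_levels)))
      stopf("covariate_los_effects must be a named list keyed by covariate")
    for (nm in names(eff)) {
      check_number(eff[[nm]], paste0("covariate_los_effects$", nm),
                   lower = 0, strict_lower = TRUE)
      if (!all(names(eff[[nm]]) %in% episode_levels[[nm]]))
        stopf("unknown level in covariate_los_effects$%s", nm)
    }
  }
  if (!is.null(cfg$seed))
    check_number(cfg$seed, "seed", allow_vector = FALSE)
  invisible(cfg)
}

#' Expected per-cell rates and LOS means implied by a generator config
#'
#' @param config a [generator_config()].
#' @return Data frame with one row per design cell: `hospital`, `year`,
#'   `presentation_rate`, `admission_rate` (per 1,000 beds per month),
#'   `ed_los_mean`, `inpatient_los_mean` (hours), `admission_prob`.
#' @export
cell_rates <- function(config) {
  cells <- expand.grid(hospital = hospital_levels, year = year_levels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hosp <- as.integer(cells$hospital == "intervention")
  post <- as.integer(cells$year == "post")
  trt <- hosp * post  # program acts only on the intervention-post cell
  scale_by <- function(base, rh, ry, rt)
    base * rh^hosp * ry^post * rt^trt
  pres <- scale_by(config$baseline_rates[["presentations"]],
                   config$hospital_rate_ratio[["presentations"]],
                   config$year_rate_ratio[["presentations"]],
                   config$intervention_rate_ratio[["presentations"]])
  adm <- scale_by(config$baseline_rates[["admissions"]],
                  config$hospital_rate_ratio[["admissions"]],
                  config$year_rate_ratio[["admissions"]],
                  config$intervention_rate_ratio[["admissions"]])
  ed_los <- scale_by(config$baseline_los_means[["ed"]],
                     config$hospital_los_ratio[["ed"]],
                     config$year_los_ratio[["ed"]],
                     config$intervention_los_ratio[["ed"]])
  ip_los <- scale_by(config$baseline_los_means[["inpatient"]],
                     config$hospital_los_ratio[["inpatient"]],
                     config$year_los_ratio[["inpatient"]],
                     config$intervention_los_ratio[["inpatient"]])
  data.frame(cells, presentation_rate = pres, admission_rate = adm,
             ed_los_mean = ed_los, inpatient_los_mean = ip_los,
             admission_prob = adm / pres, stringsAsFactors = FALSE)
}

empty_episode_frame <- function() {
  data.frame(hospital = factor(character(), hospital_levels),
             year = factor(character(), year_levels),
             month_index = integer(),
             age_group = factor(character(), episode_levels$age_group),
             gender = factor(character(), episode_levels$gender),
             triage = factor(character(), episode_levels$triage),
             diagnosis_group = factor(character(),
                                      episode_levels$diagnosis_group),
             attendance_day = factor(character(),
                                     episode_levels$attendance_day),
             attendance_time = factor(character(),
                                      episode_levels$attendance_time),
             ed_los_hours = numeric(),
             admitted = logical(),
             inpatient_los_hours = numeric(),
             stringsAsFactors = FALSE)
}

#' Generate synthetic patient ED episodes
#'
#' Draws one realization of the study design described by `config`: per
#' design cell and month, the number of ED presentations is Poisson with
#' mean `presentation_rate * beds/1000`; each episode gets independently
#' sampled covariates, a gamma ED length of stay, an admission flag
#' (per-cell admission probability = admission rate / presentation rate)
#' and, for admitted episodes, a gamma inpatient length of stay.
#'
#' @param config a [generator_config()]; with a non-`NULL` `seed` the
#'   output is reproducible.
#' @return Data frame of episode records, one row per ED presentation,
#'   with `inpatient_los_hours = NA` for non-admitted episodes.
#' @export
generate_episodes <- function(config) {
  stopifnot(inherits(config, "hinh_generator_config"))
  validate_generator_config(config)
  with_seed(config$seed, {
    rates <- cell_rates(config)
    months <- as.integer(config$months_per_period)
    cells <- lapply(seq_len(nrow(rates)), function(r) {
      row <- rates[r, ]
      n_month <- stats::rpois(months, row$presentation_rate *
                                config$beds_per_catchment / 1000)
      n <- sum(n_month)
      if (n == 0L) return(empty_episode_frame())
      ep <- data.frame(
        hospital = factor(row$hospital, hospital_levels),
        year = factor(row$year, year_levels),
        month_index = rep.int(seq_len(months), n_month),
        stringsAsFactors = FALSE)
      for (nm in names(episode_levels)) {
        p <- config$covariate_mix[[nm]][episode_levels[[nm]]]
        ep[[nm]] <- factor(sample(episode_levels[[nm]], n, replace = TRUE,
                                  prob = p), episode_levels[[nm]])
      }
      mult <- rep.int(1, n)
      if (!is.null(config$covariate_los_effects)) {
        for (nm in names(config$covariate_los_effects)) {
          eff <- config$covariate_los_effects[[nm]]
          lv <- as.character(ep[[nm]])
          mult <- mult * ifelse(lv %in% names(eff), eff[lv], 1)
        }
      }
      sh_ed <- config$los_shape[["ed"]]
      ep$ed_los_hours <- stats::rgamma(n, shape = sh_ed,
                                       rate = sh_ed / (row$ed_los_mean * mult))
      ep$admitted <- stats::rbinom(n, 1L, row$admission_prob) == 1L
      ep$inpatient_los_hours <- NA_real_
      n_adm <- sum(ep$admitted)
      if (n_adm > 0L) {
        sh_ip <- config$los_shape[["inpatient"]]
        ep$inpatient_los_hours[ep$admitted] <-
          stats::rgamma(n_adm, shape = sh_ip,
                        rate = sh_ip / (row$inpatient_los_mean *
                                          mult[ep$admitted]))
      }
      ep
    })
    out <- do.call(rbind, cells)
    rownames(out) <- NULL
    out
  })
}

#' Aggregate episodes into monthly presentation/admission counts
#'
#' @param episodes an episode data frame from [generate_episodes()].
#' @param exposure_beds RACF beds in the catchment (the rate denominator
#'   exposure attached to every month).
#' @param months_per_period number of observation months per period, so
#'   months without any episode appear with zero counts.
#' @return Data frame with one row per hospital x year x month:
#'   `n_presentations`, `n_admissions` (never exceeding presentations) and
#'   `exposure_beds`.
#' @export
aggregate_monthly_counts <- function(episodes, exposure_beds,
                                     months_per_period = max(1L,
                                       suppressWarnings(max(episodes$month_index)))) {
  check_number(exposure_beds, "exposure_beds", lower = 0, strict_lower = TRUE,
               allow_vector = FALSE)
  grid <- expand.grid(hospital = hospital_levels, year = year_levels,
                      month_index = seq_len(months_per_period),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(h, y, m) paste(h, y, m, sep = "|")
  pres <- table(key(episodes$hospital, episodes$year, episodes$month_index))
  adm_ep <- episodes[episodes$admitted, ]
  adm <- table(key(adm_ep$hospital, adm_ep$year, adm_ep$month_index))
  gk <- key(grid$hospital, grid$year, grid$month_index)
  grid$n_presentations <- as.integer(ifelse(gk %in% names(pres),
                                            pres[gk], 0L))
  grid$n_admissions <- as.integer(ifelse(gk %in% names(adm), adm[gk], 0L))
  grid$exposure_beds <- exposure_beds
  grid <- grid[order(grid$hospital, grid$year, grid$month_index), ]
  rownames(grid) <- NULL
  grid
}

#' Generate synthetic monthly utilisation counts
#'
#' Draws episodes with [generate_episodes()] and aggregates them to monthly
#' presentation and admission counts per design cell, so the episode-level
#' and month-level views describe one coherent realization (identical when
#' the config seed is fixed). Admissions therefore never exceed
#' presentations.
#'
#' @param config a [generator_config()].
#' @return Data frame as from [aggregate_monthly_counts()].
#' @export
generate_monthly_counts <- function(config) {
  stopifnot(inherits(config, "hinh_generator_config"))
  aggregate_monthly_counts(generate_episodes(config),
                           exposure_beds = config$beds_per_catchment,
                           months_per_period = config$months_per_period)
}

extract_schemas <- list(
  episodes = c("hospital", "year", "month_index", names(episode_levels),
               "ed_los_hours", "admitted", "inpatient_los_hours"),
  monthly_counts = c("hospital", "year", "month_index", "n_presentations",
                     "n_admissions", "exposure_beds"))

#' Write a data extract to CSV
#'
#' Writes an episode or monthly-count data frame as a plain UTF-8 CSV with
#' a header row; the round trip through [read_extract()] is lossless, and a
#' fixed generator seed yields byte-identical files.
#'
#' @param records data frame from the generator (either schema).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_extract <- function(records, path) {
  type <- detect_extract_type(names(records))
  utils::write.csv(records[extract_schemas[[type]]], path,
                   row.names = FALSE, quote = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

detect_extract_type <- function(cols) {
  for (type in names(extract_schemas))
    if (all(extract_schemas[[type]] %in% cols)) return(type)
  stopf("unrecognized extract schema; columns found: %s",
        paste(cols, collapse = ", "))
}

#' Read a data extract written by [write_extract()]
#'
#' Validates the schema while reading: category columns must only contain
#' known levels and numeric invariants must hold (positive lengths of stay,
#' inpatient LOS present exactly for admitted episodes, admissions not
#' exceeding presentations). Violations are reported with the offending
#' file line numbers (header = line 1).
#'
#' @param path CSV file path.
#' @param type `"episodes"` or `"monthly_counts"`; detected from the header
#'   by default.
#' @return Data frame in the generator's schema (empty if the file has only
#'   a header).
#' @export
read_extract <- function(path, type = c("auto", "episodes",
                                        "monthly_counts")) {
  type <- match.arg(type)
  if (!file.exists(path)) stopf("extract not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (type == "auto") type <- detect_extract_type(names(raw))
  missing_cols <- setdiff(extract_schemas[[type]], names(raw))
  if (length(missing_cols))
    stopf("extract %s is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  raw <- raw[extract_schemas[[type]]]
  if (nrow(raw) == 0L) {
    if (type == "episodes") return(empty_episode_frame())
    return(data.frame(hospital = character(), year = character(),
                      month_index = integer(), n_presentations = integer(),
                      n_admissions = integer(), exposure_beds = numeric(),
                      stringsAsFactors = FALSE))
  }
  lines <- function(idx) paste(idx + 1L, collapse = ", ")  # +1 for header
  check_cat <- function(col, levels) {
    bad <- which(!raw[[col]] %in% levels)
    if (length(bad))
      stopf("%s: unknown %s value(s) '%s' at line(s) %s", path, col,
            paste(unique(raw[[col]][bad]), collapse = "', '"), lines(bad))
    factor(raw[[col]], levels)
  }
  raw$hospital <- check_cat("hospital", hospital_levels)
  raw$year <- check_cat("year", year_levels)
  if (type == "episodes") {
    for (nm in names(episode_levels))
      raw[[nm]] <- check_cat(nm, episode_levels[[nm]])
    if (is.character(raw$admitted))
      raw$admitted <- as.logical(raw$admitted)
    bad <- which(is.na(raw$admitted))
    if (length(bad))
      stopf("%s: malformed 'admitted' flag at line(s) %s", path, lines(bad))
    bad <- which(!is.finite(raw$ed_los_hours) | raw$ed_los_hours <= 0)
    if (length(bad))
      stopf("%s: non-positive ed_los_hours at line(s) %s", path, lines(bad))
    bad <- which(raw$admitted & (is.na(raw$inpatient_los_hours) |
                                   raw$inpatient_los_hours <= 0))
    if (length(bad))
      stopf("%s: admitted episodes need positive inpatient_los_hours, line(s) %s",
            path, lines(bad))
    bad <- which(!raw$admitted & !is.na(raw$inpatient_los_hours))
    if (length(bad))
      stopf("%s: inpatient_los_hours present for non-admitted episodes, line(s) %s",
            path, lines(bad))
  } else {
    for (nm in c("n_presentations", "n_admissions")) {
      bad <- which(is.na(raw[[nm]]) | raw[[nm]] < 0 |
                     raw[[nm]] != as.integer(raw[[nm]]))
      if (length(bad))
        stopf("%s: malformed %s at line(s) %s", path, nm, lines(bad))
    }
    bad <- which(raw$n_admissions > raw$n_presentations)
    if (length(bad))
      stopf("%s: admissions exceed presentations at line(s) %s", path,
            lines(bad))
    bad <- which(is.na(raw$exposure_beds) | raw$exposure_beds <= 0)
    if (length(bad))
      stopf("%s: non-positive exposure_beds at line(s) %s", path, lines(bad))
  }
  raw
}
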
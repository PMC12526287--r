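#' Read a cohort FFQ response table
#'
#' CSV with first column `participant_id` and one column per item; cells are
#' frequency codes 0-8 or canonical labels (see [ffq_categories()]).
#'
#' @param path CSV path.
#' @return Response tibble.
#' @export
read_responses <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"participant_id" %in% names(out)) {
    stop("responses file ", path, " lacks a participant_id column",
         call. = FALSE)
  }
  out$participant_id <- as.character(out$participant_id)
  out
}

#' Read a food composition table
#'
#' CSV with columns `item_id`, `name`, `is_liquid` (0/1) and the 11
#' per-portion nutrient columns of [nutrient_info()].
#'
#' @param path CSV path.
#' @return Composition tibble (validated).
#' @export
read_composition <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_composition(out)
  out$is_liquid <- as.logical(out$is_liquid)
  out
}

#' Read a de-identified dry-weight sample
#'
#' Single-column CSV of weights in kg (header `weight_kg` or any single
#' name).
#'
#' @param path CSV path.
#' @return Numeric vector of weights.
#' @export
read_weights <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(out) != 1) {
    stop("weight file ", path, " must have exactly one column", call. = FALSE)
  }
  w <- as.numeric(out[[1]])
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  w
}

#' Assemble and validate an analysis configuration
#'
#' Collects every tunable of the pipeline in one validated object. Inputs
#' may be given as file paths (read at [run_pipeline()] time) or as
#' in-memory data frames / vectors.
#'
#' @param responses,composition Response and composition tables (paths or
#'   data frames).
#' @param weights Optional dry-weight sample (path or numeric vector); when
#'   absent the Monte Carlo report is skipped.
#' @param scheme [frequency_scheme()].
#' @param bands Band table ([default_bands()]).
#' @param atwater [atwater_factors()].
#' @param weight_grid Deterministic scenario grid (kg).
#' @param mc_iterations,mc_pairing Monte Carlo settings.
#' @param thresholds [guideline_thresholds()].
#' @param conf_level Confidence level for t intervals.
#' @param seed Integer seed for the Monte Carlo draws.
#' @param missing Missing-answer policy (`"never"` or `"error"`).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(responses, composition, weights = NULL,
                            scheme = frequency_scheme(),
                            bands = default_bands(),
                            atwater = atwater_factors(),
                            weight_grid = c(55, 65, 75, 85),
                            mc_iterations = 5000,
                            mc_pairing = "per_participant",
                            thresholds = guideline_thresholds(),
                            conf_level = 0.95, seed = 1L,
                            missing = c("never", "error")) {
  missing <- match.arg(missing)
  stopifnot(inherits(scheme, "frequency_scheme"))
  if (!is.numeric(weight_grid) || any(weight_grid <= 0)) {
    stop("weight_grid must be positive", call. = FALSE)
  }
  if (!is.numeric(mc_iterations) || mc_iterations < 1) {
    stop("mc_iterations must be >= 1", call. = FALSE)
  }
  if (!mc_pairing %in% c("per_participant", "shared")) {
    stop("mc_pairing must be 'per_participant' or 'shared'", call. = FALSE)
  }
  stopifnot(conf_level > 0, conf_level < 1)
  for (p in c("responses", "composition", "weights")) {
    v <- get(p)
    if (is.character(v) && !file.exists(v)) {
      stop(p, " path does not exist: ", v, call. = FALSE)
    }
  }
  structure(
    list(
      responses = responses, composition = composition, weights = weights,
      scheme = scheme, bands = bands, atwater = atwater,
      weight_grid = sort(weight_grid), mc_iterations = as.integer(mc_iterations),
      mc_pairing = mc_pairing, thresholds = thresholds,
      conf_level = conf_level, seed = as.integer(seed), missing = missing
    ),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from JSON
#'
#' Recognized keys: `responses`, `composition`, `weights` (paths, resolved
#' relative to the JSON file), `weight_grid`, `mc_iterations`, `mc_pairing`,
#' `conf_level`, `seed`, `missing`, `month_days`, `atwater` (named list),
#' `thresholds` (`protein_min`, `energy_min`), and `bands` (records with
#' `nutrient`, `lower`, `upper`, `kind`, `assumed`, `note`). Unspecified
#' settings keep package defaults.
#'
#' @param path JSON file.
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(dir, p)
  }
  bands <- if (!is.null(cfg$bands)) {
    b <- tibble::as_tibble(cfg$bands)
    b$lower <- as.numeric(b$lower)
    b$upper <- as.numeric(b$upper)
    b
  } else {
    default_bands()
  }
  at <- if (is.null(cfg$atwater)) atwater_factors() else {
    do.call(atwater_factors, as.list(cfg$atwater))
  }
  th <- if (is.null(cfg$thresholds)) guideline_thresholds() else {
    do.call(guideline_thresholds, as.list(cfg$thresholds))
  }
  analysis_config(
    responses = resolve(cfg$responses),
    composition = resolve(cfg$composition),
    weights = resolve(cfg$weights),
    scheme = frequency_scheme(cfg$month_days %||% 30),
    bands = bands, atwater = at, thresholds = th,
    weight_grid = cfg$weight_grid %||% c(55, 65, 75, 85),
    mc_iterations = cfg$mc_iterations %||% 5000,
    mc_pairing = cfg$mc_pairing %||% "per_participant",
    conf_level = cfg$conf_level %||% 0.95,
    seed = cfg$seed %||% 1L,
    missing = cfg$missing %||% "never"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full FFQ analysis pipeline
#'
#' Executes intake conversion, cohort summaries, energy shares,
#' energy-adjusted intakes (both modes), reference comparison, adequacy
#' counts, deterministic per-kg scenarios, the Monte Carlo weight
#' sensitivity analysis (when a weight sample is configured) and the
#' item-level frequency distribution. The bundle is a pure function of
#' (inputs, config, seed): identical runs give identical reports.
#'
#' @param config An [analysis_config()] (or path to a JSON config).
#' @return List of class `report_bundle` with elements `intakes`, `summary`,
#'   `energy_shares`, `energy_adjusted`, `reference_comparison`, `adequacy`,
#'   `per_kg_scenarios`, `monte_carlo` (NULL without weights),
#'   `frequency_distribution`, and `log` (seed, config hash, cohort size).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "analysis_config"))
  responses <- if (is.character(config$responses)) {
    read_responses(config$responses)
  } else {
    config$responses
  }
  composition <- if (is.character(config$composition)) {
    read_composition(config$composition)
  } else {
    config$composition
  }
  weights <- if (is.character(config$weights)) {
    read_weights(config$weights)
  } else {
    config$weights
  }

  intakes <- compute_cohort(responses, composition, config$scheme,
                            missing = config$missing)
  summary <- cohort_summary(intakes, conf_level = config$conf_level)
  shares <- energy_shares_from_summary(summary, factors = config$atwater)
  ea <- dplyr::full_join(
    per_1000kcal_ratio_of_means(summary)[, c("nutrient", "per_1000kcal")],
    per_1000kcal_participant_level(intakes)[
      , c("nutrient", "mean_per_1000kcal", "sd_per_1000kcal")],
    by = "nutrient"
  )
  ref <- reference_comparison(summary, config$bands)
  adq <- adequacy_table(intakes, config$bands)
  scen <- per_kg_scenarios(summary, weights = config$weight_grid,
                           thresholds = config$thresholds)
  mc <- if (!is.null(weights)) {
    monte_carlo_per_kg(
      intakes, weights, iterations = config$mc_iterations,
      seed = config$seed, pairing = config$mc_pairing
    )
  } else {
    NULL
  }
  freq <- frequency_distribution(responses)

  cfg_for_hash <- config
  cfg_for_hash$responses <- responses
  cfg_for_hash$composition <- composition
  cfg_for_hash$weights <- weights
  structure(
    list(
      intakes = intakes, summary = summary, energy_shares = shares,
      energy_adjusted = ea, reference_comparison = ref, adequacy = adq,
      per_kg_scenarios = scen, monte_carlo = mc,
      frequency_distribution = freq,
      log = list(
        seed = config$seed,
        config_hash = rlang::hash(cfg_for_hash),
        n_participants = nrow(intakes)
      )
    ),
    class = "report_bundle"
  )
}

#' Write a report bundle as CSV files
#'
#' One CSV per report plus `run_log.json` (seed, config hash, cohort size).
#' All reports are computed before anything is written, so a failing stage
#' leaves no partial output.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  reports <- c(
    "intakes", "summary", "energy_shares", "energy_adjusted",
    "reference_comparison", "adequacy", "per_kg_scenarios", "monte_carlo",
    "frequency_distribution"
  )
  paths <- character(0)
  for (r in reports) {
    if (is.null(bundle[[r]])) next
    p <- file.path(dir, paste0(r, ".csv"))
    readr::write_csv(bundle[[r]], p, progress = FALSE)
    paths <- c(paths, p)
  }
  logp <- file.path(dir, "run_log.json")
  jsonlite::write_json(bundle$log, logp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, logp))
}

#' Write a complete synthetic fixture set
#'
#' Generates a composition table, a calibrated response cohort and a weight
#' sample, writes them (plus a ready-to-run JSON config) into `dir`, and
#' returns the config path. The files use exactly the CSV schemas the
#' readers expect, so `run_pipeline(simulate_fixture_set(dir, seed))`
#' exercises the full round trip.
#'
#' @param dir Output directory.
#' @param seed Integer seed driving all three generators.
#' @param n Participants (default 50).
#' @param n_items FFQ items (default 55).
#' @param targets Intake targets ([cohort_targets()]).
#' @param liquid_fraction Share of liquid items (default 0.2).
#' @param weights_model [weight_model()] for the weight sample.
#' @param mc_iterations Monte Carlo iterations recorded in the config.
#' @param calibrate Calibrate the response generator to the targets
#'   (default TRUE; disable for small structural fixtures, where sample
#'   moments are too noisy to pin).
#' @return Path of the written `config.json`, invisibly.
#' @export
simulate_fixture_set <- function(dir, seed, n = 50, n_items = 55,
                                 targets = cohort_targets(),
                                 liquid_fraction = 0.2,
                                 weights_model = weight_model(),
                                 mc_iterations = 5000, calibrate = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  comp <- generate_composition(seed = seed, n_items = n_items,
                               liquid_fraction = liquid_fraction)
  cohort <- generate_responses(comp, targets = targets, n = n,
                               seed = seed + 1, calibrate = calibrate)
  w <- generate_weights(weights_model, seed = seed + 2)
  readr::write_csv(cohort$composition, file.path(dir, "composition.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$responses, file.path(dir, "responses.csv"),
                   progress = FALSE)
  readr::write_csv(tibble::tibble(weight_kg = w),
                   file.path(dir, "weights.csv"), progress = FALSE)
  cfg <- list(
    responses = "responses.csv", composition = "composition.csv",
    weights = "weights.csv", mc_iterations = mc_iterations,
    seed = seed
  )
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(cfg_path)
}
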
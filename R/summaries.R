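#' Descriptive summary of one nutrient across a cohort
#'
#' Mean, two-sided Student-t 95% confidence interval, median, sample SD
#' (n - 1 denominator), minimum and maximum. The confidence interval is
#' `mean +/- t(1 - alpha/2, n - 1) * sd / sqrt(n)`; with fewer than two
#' values the interval degenerates to the mean and a warning is raised.
#'
#' @param values Numeric vector of per-participant daily amounts.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `n`, `mean`, `ci_lower`, `ci_upper`, `median`,
#'   `sd`, `min`, `max`.
#' @export
#' @examples
#' summarize_nutrient(c(10, 20, 30))
summarize_nutrient <- function(values, conf_level = 0.95) {
  stopifnot(is.numeric(values), conf_level > 0, conf_level < 1)
  if (any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  n <- length(values)
  m <- mean(values)
  if (n < 2) {
    warning("fewer than 2 values: confidence interval degenerates to the mean",
            call. = FALSE)
    s <- if (n == 1) 0 else NA_real_
    lo <- hi <- m
  } else {
    s <- stats::sd(values)
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
    lo <- m - half
    hi <- m + half
  }
  tibble::tibble(
    n = n, mean = m, ci_lower = lo, ci_upper = hi,
    median = stats::median(values), sd = s,
    min = if (n) min(values) else NA_real_,
    max = if (n) max(values) else NA_real_
  )
}

#' Cohort summary table (one row per dietary component)
#'
#' Applies [summarize_nutrient()] to each of the 11 components and, by
#' default, to free fluid. This is the descriptive table around which the
#' downstream analyses (per-kg scenarios, energy adjustment, reference
#' comparison) are built.
#'
#' @param intakes Intake tibble from [compute_cohort()].
#' @param conf_level Confidence level for the t interval.
#' @param include_free_fluid Add a `free_fluid` row computed on
#'   `free_fluid_ml`? Default `TRUE`.
#' @return Tibble with columns `nutrient`, `n`, `mean`, `ci_lower`,
#'   `ci_upper`, `median`, `sd`, `min`, `max`.
#' @export
cohort_summary <- function(intakes, conf_level = 0.95,
                           include_free_fluid = TRUE) {
  stopifnot(is.data.frame(intakes), nrow(intakes) >= 1)
  keys <- .nutrients$nutrient
  cols <- .nutrients$column
  if (include_free_fluid && "free_fluid_ml" %in% names(intakes)) {
    keys <- c(keys, "free_fluid")
    cols <- c(cols, "free_fluid_ml")
  }
  rows <- lapply(cols, function(cl) {
    summarize_nutrient(intakes[[cl]], conf_level = conf_level)
  })
  dplyr::bind_cols(
    tibble::tibble(nutrient = keys),
    dplyr::bind_rows(rows)
  )
}

#' Atwater energy-conversion factors
#'
#' Per-gram metabolizable energy of the macronutrients: 4 kcal/g for protein
#' and carbohydrate, 9 kcal/g for fat, 2 kcal/g for fiber.
#'
#' @param protein,fat,carbohydrate,fiber kcal per gram; all must be > 0.
#' @return Named numeric vector of length 4.
#' @export
atwater_factors <- function(protein = 4, fat = 9, carbohydrate = 4,
                            fiber = 2) {
  f <- c(protein = protein, fat = fat, carbohydrate = carbohydrate,
         fiber = fiber)
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("Atwater factors must be positive", call. = FALSE)
  }
  f
}

#' Macronutrient energy shares (%E)
#'
#' Percentage of dietary energy contributed by protein, fat, carbohydrate
#' and fiber, computed with Atwater factors. The denominator is the
#' Atwater-derived total `sum(factor * grams)`, so the four shares sum to
#' exactly 100 before rounding.
#'
#' @param protein_g,fat_g,carb_g,fiber_g Mean daily intakes in grams.
#' @param factors Factors from [atwater_factors()].
#' @return One-row tibble: `protein_pct`, `fat_pct`, `carbohydrate_pct`,
#'   `fiber_pct`.
#' @export
#' @examples
#' energy_shares(87.7, 136.6, 267.7, 21.6)
energy_shares <- function(protein_g, fat_g, carb_g, fiber_g,
                          factors = atwater_factors()) {
  g <- c(protein_g, fat_g, carb_g, fiber_g)
  stopifnot(is.numeric(g), length(g) == 4)
  if (any(g < 0)) stop("macronutrient intakes must be >= 0", call. = FALSE)
  kcal <- factors[c("protein", "fat", "carbohydrate", "fiber")] * g
  total <- sum(kcal)
  if (total <= 0) {
    stop("all macronutrient intakes are zero: energy shares undefined",
         call. = FALSE)
  }
  pct <- 100 * kcal / total
  tibble::tibble(
    protein_pct = pct[["protein"]],
    fat_pct = pct[["fat"]],
    carbohydrate_pct = pct[["carbohydrate"]],
    fiber_pct = pct[["fiber"]]
  )
}

# %E from a cohort summary table (uses the mean column).
energy_shares_from_summary <- function(summary, factors = atwater_factors()) {
  m <- stats::setNames(summary$mean, summary$nutrient)
  energy_shares(m[["protein"]], m[["fat"]], m[["carbohydrate"]],
                m[["fiber"]], factors = factors)
}

#' Energy-adjusted intakes: ratio of cohort means
#'
#' Nutrient density per 1000 kcal computed from cohort means:
#' `1000 * mean(nutrient) / mean(energy)`. The energy row self-normalizes to
#' exactly 1000. This is the mode whose values match a table built from a
#' cohort-mean column.
#'
#' @param summary Cohort summary tibble from [cohort_summary()] (needs
#'   `nutrient` and `mean`).
#' @param nutrients Which nutrients to adjust (default: all rows of
#'   `summary` except free fluid; water is retained).
#' @return Tibble: `nutrient`, `per_1000kcal`, `mode = "ratio_of_means"`.
#' @export
per_1000kcal_ratio_of_means <- function(summary, nutrients = NULL) {
  stopifnot(all(c("nutrient", "mean") %in% names(summary)))
  e <- summary$mean[summary$nutrient == "energy"]
  if (length(e) != 1 || !is.finite(e) || e <= 0) {
    stop("cohort mean energy must be a single positive value", call. = FALSE)
  }
  rows <- summary[summary$nutrient != "free_fluid", ]
  if (!is.null(nutrients)) rows <- rows[rows$nutrient %in% nutrients, ]
  tibble::tibble(
    nutrient = rows$nutrient,
    per_1000kcal = 1000 * rows$mean / e,
    mode = "ratio_of_means"
  )
}

#' Energy-adjusted intakes: participant-level standardization
#'
#' Each participant's intake is divided by that participant's own energy
#' intake (`1000 * x_i / e_i`); the per-1000 kcal ratios are then summarized
#' as mean and sample SD across participants. Participants with zero energy
#' are excluded with a warning. Unlike the ratio-of-means mode this captures
#' between-person variability in nutrient density.
#'
#' @param intakes Intake tibble from [compute_cohort()].
#' @return Tibble: `nutrient`, `mean_per_1000kcal`, `sd_per_1000kcal`,
#'   `n_used`, `mode = "participant_level"`.
#' @export
per_1000kcal_participant_level <- function(intakes) {
  stopifnot(is.data.frame(intakes), nrow(intakes) >= 1)
  e <- intakes$energy_kcal
  keep <- is.finite(e) & e > 0
  if (any(!keep)) {
    warning(
      sum(!keep), " participant(s) with zero energy intake excluded from",
      " per-1000 kcal standardization", call. = FALSE
    )
  }
  if (!any(keep)) {
    stop("no participants with positive energy intake", call. = FALSE)
  }
  sub <- intakes[keep, ]
  rows <- lapply(seq_len(nrow(.nutrients)), function(i) {
    r <- 1000 * sub[[.nutrients$column[i]]] / sub$energy_kcal
    tibble::tibble(
      nutrient = .nutrients$nutrient[i],
      mean_per_1000kcal = mean(r),
      sd_per_1000kcal = if (length(r) > 1) stats::sd(r) else 0,
      n_used = length(r)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$mode <- "participant_level"
  out
}

#' Item-level frequency-of-consumption distribution
#'
#' For every FFQ item, the count and percentage of the cohort in each of the
#' nine frequency categories.
#'
#' @param responses Response tibble (as accepted by [compute_cohort()]).
#' @return Long tibble: `item_id`, `code`, `label`, `n`, `pct`. Counts sum
#'   to the cohort size within each item.
#' @export
frequency_distribution <- function(responses) {
  stopifnot(is.data.frame(responses))
  if (nrow(responses) == 0) {
    stop("cannot tabulate frequencies for an empty cohort", call. = FALSE)
  }
  items <- setdiff(names(responses), "participant_id")
  if (!length(items)) stop("responses contain no item columns", call. = FALSE)
  n_cohort <- nrow(responses)
  cats <- ffq_categories()
  rows <- lapply(items, function(it) {
    codes <- resolve_codes(responses[[it]], "never", item = it)
    counts <- tabulate(codes + 1L, nbins = 9L)
    tibble::tibble(
      item_id = it, code = cats$code, label = cats$label,
      n = counts, pct = 100 * counts / n_cohort
    )
  })
  dplyr::bind_rows(rows)
}
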
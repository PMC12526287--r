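# Fixed set of assessed dietary components and their storage columns.
# Order matters: it is the reporting order of the cohort tables.
.nutrients <- data.frame(
  nutrient = c(
    "water", "energy", "protein", "fat", "carbohydrate", "fiber",
    "calcium", "magnesium", "phosphorus", "potassium", "sodium"
  ),
  column = c(
    "water_ml", "energy_kcal", "protein_g", "fat_g", "carb_g", "fiber_g",
    "ca_mg", "mg_mg", "p_mg", "k_mg", "na_mg"
  ),
  unit = c("mL", "kcal", "g", "g", "g", "g", "mg", "mg", "mg", "mg", "mg"),
  label = c(
    "Water [mL]", "Energy [kcal]", "Protein [g]", "Fat [g]",
    "Carbohydrates [g]", "Fiber [g]", "Ca [mg]", "Mg [mg]", "P [mg]",
    "K [mg]", "Na [mg]"
  ),
  stringsAsFactors = FALSE
)

#' Assessed dietary components
#'
#' The 11 components estimated from the FFQ, with the CSV column name used
#' for each in composition tables and intake outputs, the unit, and a display
#' label. The set is fixed: water (mL), energy (kcal), protein, fat,
#' carbohydrate and fiber (g), and calcium, magnesium, phosphorus, potassium
#' and sodium (mg).
#'
#' @return A tibble with columns `nutrient`, `column`, `unit`, `label`.
#' @export
#' @examples
#' nutrient_info()
nutrient_info <- function() {
  tibble::as_tibble(.nutrients)
}

#' Default cohort intake targets for the synthetic generator
#'
#' Per-nutrient target means and standard deviations of daily intake used as
#' defaults by [generate_responses()]. The defaults describe a 50-adult
#' maintenance-HD cohort with adequate mean energy (about 2697 kcal/day) and
#' protein (about 88 g/day) but a fat-dominant, high-sodium profile — the
#' marginal structure the rest of the package is designed to summarize.
#'
#' @return A tibble with columns `nutrient`, `mean`, `sd` (daily-intake units
#'   of each nutrient, see [nutrient_info()]).
#' @export
#' @examples
#' cohort_targets()
cohort_targets <- function() {
  tibble::tibble(
    nutrient = .nutrients$nutrient,
    mean = c(851.3, 2696.9, 87.7, 136.6, 267.7, 21.6,
             933.9, 328.5, 1344.3, 2393.1, 3018.9),
    sd = c(356.5, 1392.7, 35.3, 115.4, 128.0, 8.9,
           408.3, 135.1, 526.9, 995.8, 1658.2)
  )
}
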
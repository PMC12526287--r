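#' Operational reference bands for descriptive adequacy labelling
#'
#' Study-style operational intake bands used to label daily intakes as
#' deficient / adequate / excess. These are descriptive categories, not
#' clinical prescriptions:
#'
#' * energy 1500-3200 kcal, protein 40-120 g, fat 45-96 g,
#'   carbohydrate 275-440 g, fiber 25-50 g (two-sided bands);
#' * free fluid: notional upper threshold of 700 mL/day (no lower bound —
#'   a "deficient" label is never emitted for fluid);
#' * sodium: fixed guideline limit of 2300 mg/day (2.3 g/day); the lower
#'   bound of 1500 mg is an explicit assumption (`assumed = TRUE`) because
#'   only the upper limit is guideline-backed;
#' * potassium 2000-3000 mg, phosphorus 800-1200 mg, calcium 1000-1500 mg:
#'   nephrology guidance individualizes these to serum values, so the
#'   numeric bands here are assumed operational ranges for tabulation only;
#' * magnesium carries no band anywhere and is summarized but never
#'   classified.
#'
#' Total water is also left unbanded: fluid adequacy is judged on free
#' fluid, the clinically relevant quantity.
#'
#' @return Tibble: `nutrient`, `lower`, `upper` (NA when absent), `kind`
#'   (`two_sided`, `upper_threshold`, `lower_threshold`, `individualized`),
#'   `assumed` (logical), `note`.
#' @export
#' @examples
#' default_bands()
default_bands <- function() {
  tibble::tribble(
    ~nutrient,      ~lower, ~upper, ~kind,             ~assumed, ~note,
    "energy",         1500,   3200, "two_sided",        FALSE, "operational band",
    "protein",          40,    120, "two_sided",        FALSE, "operational band",
    "fat",              45,     96, "two_sided",        FALSE, "operational band",
    "carbohydrate",    275,    440, "two_sided",        FALSE, "operational band",
    "fiber",            25,     50, "two_sided",        FALSE, "operational band",
    "free_fluid",       NA,    700, "upper_threshold",  FALSE, "notional threshold; clinical targets are individualized",
    "sodium",         1500,   2300, "two_sided",        TRUE,  "upper limit guideline-backed (<=2.3 g/day); lower bound assumed",
    "potassium",      2000,   3000, "individualized",   TRUE,  "assumed operational band; guidance individualizes to serum K",
    "phosphorus",      800,   1200, "individualized",   TRUE,  "assumed operational band; guidance individualizes to serum P",
    "calcium",        1000,   1500, "individualized",   TRUE,  "assumed operational band; avoid hypercalcemia"
  )
}

check_band <- function(lower, upper) {
  if (!is.na(lower) && !is.na(upper) && lower >= upper) {
    stop("band lower bound must be below upper bound", call. = FALSE)
  }
}

#' Classify a value against a reference band
#'
#' `value < lower` is deficient, `value > upper` is excess, anything else is
#' adequate; bounds are inclusive, so a value exactly on a bound is
#' adequate. A threshold-style band (one bound absent) never emits the
#' missing side's label. A band with no bounds at all yields `NA` ("not
#' classifiable").
#'
#' @param value Numeric vector of intake values.
#' @param lower,upper Band limits (NA for absent).
#' @return Character vector: `"deficient"`, `"adequate"`, `"excess"`, or NA.
#' @export
#' @examples
#' classify_value(c(30, 85, 130), lower = 40, upper = 120)
classify_value <- function(value, lower = NA_real_, upper = NA_real_) {
  stopifnot(is.numeric(value))
  check_band(lower, upper)
  if (is.na(lower) && is.na(upper)) {
    return(rep(NA_character_, length(value)))
  }
  out <- rep("adequate", length(value))
  if (!is.na(lower)) out[value < lower] <- "deficient"
  if (!is.na(upper)) out[value > upper] <- "excess"
  out[is.na(value)] <- NA_character_
  out
}

# intake column corresponding to a band's nutrient key
band_column <- function(nutrient) {
  ifelse(
    nutrient == "free_fluid", "free_fluid_ml",
    .nutrients$column[match(nutrient, .nutrients$nutrient)]
  )
}

#' Per-participant adequacy counts (deficient / adequate / excess)
#'
#' Classifies every participant's intake of each banded nutrient and
#' tabulates counts and percentages per label. Free fluid is classified on
#' `free_fluid_ml`, not on total water. Nutrients without a band (e.g.
#' magnesium) are omitted with a message.
#'
#' @param intakes Intake tibble from [compute_cohort()].
#' @param bands Band table in the shape of [default_bands()].
#' @return Tibble: `nutrient`, `n`, then `deficient_n`, `deficient_pct`,
#'   `adequate_n`, `adequate_pct`, `excess_n`, `excess_pct`. Counts sum to
#'   `n` in every row.
#' @export
adequacy_table <- function(intakes, bands = default_bands()) {
  stopifnot(is.data.frame(intakes))
  if (nrow(intakes) == 0) stop("empty cohort", call. = FALSE)
  n <- nrow(intakes)
  rows <- lapply(seq_len(nrow(bands)), function(i) {
    b <- bands[i, ]
    col <- band_column(b$nutrient)
    if (is.na(col) || !col %in% names(intakes)) {
      return(NULL)
    }
    if (is.na(b$lower) && is.na(b$upper)) {
      message("nutrient ", b$nutrient, " has no operational bounds; skipped")
      return(NULL)
    }
    lab <- classify_value(intakes[[col]], b$lower, b$upper)
    counts <- vapply(
      c("deficient", "adequate", "excess"),
      function(l) sum(lab == l, na.rm = TRUE), integer(1)
    )
    tibble::tibble(
      nutrient = b$nutrient, n = n,
      deficient_n = counts[["deficient"]],
      deficient_pct = 100 * counts[["deficient"]] / n,
      adequate_n = counts[["adequate"]],
      adequate_pct = 100 * counts[["adequate"]] / n,
      excess_n = counts[["excess"]],
      excess_pct = 100 * counts[["excess"]] / n
    )
  })
  dplyr::bind_rows(rows)
}

#' Qualitative comparison of cohort means with reference bands
#'
#' One row per banded nutrient with the cohort mean and median and the
#' adequacy label of the mean — the qualitative "level" column of a
#' reference-comparison table.
#'
#' @param summary Cohort summary from [cohort_summary()].
#' @param bands Band table in the shape of [default_bands()].
#' @return Tibble: `nutrient`, `mean`, `median`, `level`, `assumed`.
#' @export
reference_comparison <- function(summary, bands = default_bands()) {
  stopifnot(all(c("nutrient", "mean", "median") %in% names(summary)))
  rows <- dplyr::inner_join(
    summary[, c("nutrient", "mean", "median")],
    bands[, c("nutrient", "lower", "upper", "assumed")],
    by = "nutrient"
  )
  rows$level <- vapply(
    seq_len(nrow(rows)),
    function(i) classify_value(rows$mean[i], rows$lower[i], rows$upper[i]),
    character(1)
  )
  rows[, c("nutrient", "mean", "median", "level", "assumed")]
}
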
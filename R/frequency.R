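#' The nine FFQ consumption-frequency categories
#'
#' Ordered category table used throughout the package. Codes 0-8 form a total
#' order of increasing consumption frequency. Code 0 covers both "never" and
#' "less than once per month" (both carry a zero multiplier); code 1 is the
#' "1-3 times per month" category.
#'
#' @return A tibble with integer `code` (0-8) and character `label`.
#' @export
#' @examples
#' ffq_categories()
ffq_categories <- function() {
  tibble::tibble(
    code = 0:8,
    label = c(
      "never", "1-3 per month", "1 per week", "2-4 per week",
      "5-6 per week", "1 per day", "2-3 per day", "4-5 per day",
      ">5 per day"
    )
  )
}

#' Frequency-to-daily conversion scheme
#'
#' Maps each frequency category to a per-day multiplier. Sub-daily categories
#' are expressed as exact occasions-per-month fractions over the month length
#' (default 30 days): 0, 2/30, 4.5/30, 13.5/30, 22.5/30; the daily categories
#' carry 1, 2.5, 4.5 and 6. Multipliers are stored as exact ratios — never as
#' pre-rounded decimals such as 0.067 — so repeated summation does not
#' accumulate rounding drift.
#'
#' @param month_days Number of days assumed per month (default 30).
#' @return An object of class `frequency_scheme`: a list with `multipliers`
#'   (named numeric, one per category in code order) and `month_days`.
#' @export
#' @examples
#' frequency_scheme()$multipliers
frequency_scheme <- function(month_days = 30) {
  if (!is.numeric(month_days) || length(month_days) != 1 || month_days <= 0) {
    stop("`month_days` must be a single positive number", call. = FALSE)
  }
  per_month <- c(0, 2, 4.5, 13.5, 22.5)
  mult <- c(per_month / month_days, 1, 2.5, 4.5, 6)
  structure(
    list(
      multipliers = stats::setNames(mult, ffq_categories()$label),
      month_days = month_days
    ),
    class = "frequency_scheme"
  )
}

#' Per-day multiplier for a frequency category
#'
#' @param category Integer category code(s) 0-8, or canonical label(s) as in
#'   [ffq_categories()]. Vectorized.
#' @param scheme A [frequency_scheme()].
#' @return Numeric vector of per-day multipliers.
#' @export
#' @examples
#' multiplier_for(c(0L, 3L, 8L))       # 0, 0.45, 6
#' multiplier_for("2-3 per day")       # 2.5
multiplier_for <- function(category, scheme = frequency_scheme()) {
  stopifnot(inherits(scheme, "frequency_scheme"))
  cats <- ffq_categories()
  if (is.character(category)) {
    idx <- match(category, cats$label)
  } else {
    idx <- match(as.integer(category), cats$code)
  }
  if (anyNA(idx)) {
    bad <- unique(category[is.na(idx)])
    stop(
      "unknown frequency category: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  unname(scheme$multipliers[idx])
}
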
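#' Per-kg intake guideline thresholds
#'
#' Minimum per-kilogram daily targets for maintenance hemodialysis:
#' protein 1.2 g/kg/day and energy 35 kcal/kg/day.
#'
#' @param protein_min,energy_min Positive thresholds.
#' @return Named numeric vector `c(protein = ..., energy = ...)`.
#' @export
guideline_thresholds <- function(protein_min = 1.2, energy_min = 35) {
  th <- c(protein = protein_min, energy = energy_min)
  if (any(!is.finite(th)) || any(th <= 0)) {
    stop("guideline thresholds must be positive", call. = FALSE)
  }
  th
}

#' Flag a per-kg intake against its guideline threshold
#'
#' @param per_kg_value Non-negative per-kg daily value(s).
#' @param which `"protein"` (g/kg/day) or `"energy"` (kcal/kg/day).
#' @param thresholds From [guideline_thresholds()].
#' @return Character vector: `"meets"` (value >= threshold, inclusive) or
#'   `"below"`.
#' @export
#' @examples
#' guideline_flags(c(1.59, 1.03), "protein")
guideline_flags <- function(per_kg_value, which = c("protein", "energy"),
                            thresholds = guideline_thresholds()) {
  which <- match.arg(which)
  stopifnot(is.numeric(per_kg_value))
  if (any(per_kg_value < 0, na.rm = TRUE)) {
    stop("per-kg values must be >= 0", call. = FALSE)
  }
  ifelse(per_kg_value >= thresholds[[which]], "meets", "below")
}

#' Deterministic per-kg intake scenarios over a dry-weight grid
#'
#' Divides the cohort mean and confidence bounds of each selected nutrient
#' by each assumed dry weight, yielding per-kg daily intakes under fixed
#' weight scenarios. Because the transform is a positive scalar division,
#' the interval ordering is preserved and per-kg values strictly decrease
#' along an ascending weight grid.
#'
#' @param summary Cohort summary tibble ([cohort_summary()]); needs columns
#'   `nutrient`, `mean`, `ci_lower`, `ci_upper`.
#' @param weights Positive dry weights in kg (default 55, 65, 75, 85).
#' @param nutrients Which nutrients to scale (default protein and energy,
#'   the two with per-kg guideline targets).
#' @param thresholds Optional [guideline_thresholds()] used to flag the mean
#'   for protein and energy rows.
#' @return Tibble: `nutrient`, `weight_kg`, `mean_per_kg`,
#'   `ci_lower_per_kg`, `ci_upper_per_kg`, `flag` (NA for nutrients without
#'   a per-kg guideline).
#' @export
per_kg_scenarios <- function(summary, weights = c(55, 65, 75, 85),
                             nutrients = c("protein", "energy"),
                             thresholds = guideline_thresholds()) {
  stopifnot(all(c("nutrient", "mean", "ci_lower", "ci_upper") %in%
                  names(summary)))
  if (!is.numeric(weights) || !length(weights) ||
      any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  weights <- sort(weights)
  rows <- summary[summary$nutrient %in% nutrients, ]
  if (!nrow(rows)) stop("no matching nutrients in summary", call. = FALSE)
  out <- tidyr::crossing(
    rows[, c("nutrient", "mean", "ci_lower", "ci_upper")],
    weight_kg = weights
  )
  out <- dplyr::mutate(
    out,
    mean_per_kg = .data$mean / .data$weight_kg,
    ci_lower_per_kg = .data$ci_lower / .data$weight_kg,
    ci_upper_per_kg = .data$ci_upper / .data$weight_kg
  )
  out$flag <- NA_character_
  for (w in intersect(out$nutrient, names(thresholds))) {
    i <- out$nutrient == w
    out$flag[i] <- guideline_flags(out$mean_per_kg[i], w, thresholds)
  }
  out[, c("nutrient", "weight_kg", "mean_per_kg", "ci_lower_per_kg",
          "ci_upper_per_kg", "flag")]
}

#' Monte Carlo per-kg intakes under dry-weight uncertainty
#'
#' Dietary intakes and body weights come from unlinked sources (anonymous
#' questionnaires vs. an aggregate unit-level weight distribution), so per-kg
#' intakes are simulated: in each iteration one dry weight is drawn with
#' replacement from `weights` for every participant (default pairing), each
#' participant's intake is divided by the drawn weight, and the cohort
#' median per nutrient is recorded as the iteration statistic. Across
#' iterations the statistics are summarized as their median, a 95%
#' uncertainty interval (2.5th/97.5th percentiles) and the interquartile
#' range (25th/75th). Percentiles use linear interpolation between order
#' statistics (`quantile()` type 7) so results are exactly reproducible
#' under a fixed seed.
#'
#' With `pairing = "shared"` a single weight is drawn per iteration and
#' applied to all participants, a coarser alternative for when the cohort is
#' assumed homogeneous in weight within an iteration.
#'
#' @param intakes Intake tibble from [compute_cohort()].
#' @param weights Numeric vector of positive dry weights (kg) describing the
#'   aggregate distribution resampled from.
#' @param iterations Number of Monte Carlo iterations (default 5000).
#' @param seed Optional integer seed; when supplied the draw stream is fixed
#'   (weights are drawn participants-within-iteration) and results are
#'   reproducible without touching the caller's RNG state.
#' @param pairing `"per_participant"` (default) or `"shared"`.
#' @param nutrients Nutrients to summarize (default: protein, energy,
#'   sodium, potassium, phosphorus, calcium).
#' @param keep_iterations Attach the iteration-statistic matrix as attribute
#'   `"iterations"`? Default `FALSE`.
#' @return Tibble: `nutrient`, `median_per_kg`, `ui_lower`, `ui_upper`,
#'   `iqr_lower`, `iqr_upper`. For every nutrient
#'   `ui_lower <= iqr_lower <= median <= iqr_upper <= ui_upper`.
#' @export
monte_carlo_per_kg <- function(intakes, weights, iterations = 5000,
                               seed = NULL,
                               pairing = c("per_participant", "shared"),
                               nutrients = c("protein", "energy", "sodium",
                                             "potassium", "phosphorus",
                                             "calcium"),
                               keep_iterations = FALSE) {
  pairing <- match.arg(pairing)
  stopifnot(is.data.frame(intakes))
  n <- nrow(intakes)
  if (n == 0) stop("empty cohort", call. = FALSE)
  if (!is.numeric(weights) || !length(weights) ||
      any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weight sample must contain positive finite values", call. = FALSE)
  }
  if (!is.numeric(iterations) || length(iterations) != 1 || iterations < 1) {
    stop("iterations must be >= 1", call. = FALSE)
  }
  iterations <- as.integer(iterations)
  cols <- .nutrients$column[match(nutrients, .nutrients$nutrient)]
  if (anyNA(cols)) {
    stop(
      "unknown nutrient(s): ",
      paste(nutrients[is.na(cols)], collapse = ", "), call. = FALSE
    )
  }

  draw <- function() {
    if (pairing == "per_participant") {
      # column-major fill: participants within iteration, iterations outer
      matrix(
        weights[sample.int(length(weights), n * iterations, replace = TRUE)],
        nrow = n, ncol = iterations
      )
    } else {
      matrix(
        weights[sample.int(length(weights), iterations, replace = TRUE)],
        nrow = n, ncol = iterations, byrow = TRUE
      )
    }
  }
  w <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  stats_mat <- vapply(seq_along(cols), function(k) {
    per_kg <- intakes[[cols[k]]] / w
    if (n == 1) as.numeric(per_kg) else apply(per_kg, 2, stats::median)
  }, numeric(iterations))
  if (iterations == 1) stats_mat <- matrix(stats_mat, nrow = 1)
  colnames(stats_mat) <- nutrients

  qs <- apply(stats_mat, 2, stats::quantile,
              probs = c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7)
  out <- tibble::tibble(
    nutrient = nutrients,
    median_per_kg = unname(qs["50%", ]),
    ui_lower = unname(qs["2.5%", ]),
    ui_upper = unname(qs["97.5%", ]),
    iqr_lower = unname(qs["25%", ]),
    iqr_upper = unname(qs["75%", ])
  )
  if (keep_iterations) attr(out, "iterations") <- stats_mat
  out
}
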
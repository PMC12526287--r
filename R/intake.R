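# Resolve raw response cells (integer codes, numeric, or canonical labels)
# to integer codes 0-8. NA handling follows the missing-answer policy.
resolve_codes <- function(x, missing = c("never", "error"), item = "<item>") {
  missing <- match.arg(missing)
  if (is.character(x)) {
    cats <- ffq_categories()
    idx <- match(x, cats$label)
    num <- suppressWarnings(as.integer(x))
    idx[is.na(idx)] <- match(num[is.na(idx)], cats$code)
    out <- cats$code[idx]
    out[is.na(x)] <- NA_integer_
  } else {
    out <- as.integer(x)
    bad <- !is.na(out) & !(out %in% 0:8)
    if (any(bad)) {
      stop(
        "invalid frequency code(s) for item ", item, ": ",
        paste(unique(out[bad]), collapse = ", "), call. = FALSE
      )
    }
  }
  if (is.character(x)) {
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      stop(
        "invalid frequency value(s) for item ", item, ": ",
        paste(unique(x[bad]), collapse = ", "), call. = FALSE
      )
    }
  }
  if (anyNA(out)) {
    if (missing == "error") {
      stop("missing answer(s) for item ", item, call. = FALSE)
    }
    warning(
      sum(is.na(out)), " missing answer(s) for item ", item,
      " treated as 'never'", call. = FALSE
    )
    out[is.na(out)] <- 0L
  }
  out
}

check_composition <- function(composition) {
  stopifnot(is.data.frame(composition))
  required <- c("item_id", "is_liquid", .nutrients$column)
  miss <- setdiff(required, names(composition))
  if (length(miss)) {
    stop(
      "composition table lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(composition$item_id)) {
    stop("duplicate item_id in composition table", call. = FALSE)
  }
  vals <- as.matrix(composition[, .nutrients$column])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("per-portion nutrient amounts must be finite and >= 0", call. = FALSE)
  }
  invisible(composition)
}

#' Convert a cohort of FFQ responses into daily nutrient intakes
#'
#' For every participant, each item's per-portion nutrient vector is scaled
#' by the per-day multiplier of the reported frequency category and summed
#' across items. Free fluid is the water contributed by items flagged as
#' liquid (beverages and liquid foods such as water, tea, coffee, soups,
#' milk); water naturally present in solid foods is excluded, because the
#' clinically relevant quantity in hemodialysis is free-fluid consumption
#' driving interdialytic weight gain.
#'
#' @param responses Data frame with a `participant_id` column followed by one
#'   column per FFQ item; cells are category codes 0-8 (or canonical labels).
#'   Participant ids must be unique. Items present in the composition table
#'   but absent from `responses` are resolved by the missing-answer policy.
#' @param composition Food composition table: one row per item with columns
#'   `item_id`, `name` (optional), `is_liquid` (0/1 or logical), and the 11
#'   per-portion amounts named as in [nutrient_info()].
#' @param scheme A [frequency_scheme()].
#' @param missing Missing-answer policy: `"never"` (default) treats missing
#'   answers as category 0 with a warning; `"error"` fails instead.
#' @return A tibble with one row per participant: `participant_id`, the 11
#'   daily totals (columns as in [nutrient_info()]) and `free_fluid_ml`.
#' @export
#' @examples
#' comp <- generate_composition(seed = 1, n_items = 5)
#' resp <- tibble::tibble(participant_id = "p1")
#' resp[comp$item_id] <- as.list(c(5L, 0L, 0L, 0L, 0L))
#' compute_cohort(resp, comp)
compute_cohort <- function(responses, composition,
                           scheme = frequency_scheme(),
                           missing = c("never", "error")) {
  missing <- match.arg(missing)
  check_composition(composition)
  stopifnot(is.data.frame(responses))
  if (!"participant_id" %in% names(responses)) {
    stop("responses must have a participant_id column", call. = FALSE)
  }
  ids <- as.character(responses$participant_id)
  if (anyDuplicated(ids)) {
    stop(
      "duplicate participant_id: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE
    )
  }
  item_cols <- setdiff(names(responses), "participant_id")
  unknown <- setdiff(item_cols, composition$item_id)
  if (length(unknown)) {
    stop(
      "response item(s) absent from composition table: ",
      paste(unknown, collapse = ", "), call. = FALSE
    )
  }
  absent <- setdiff(composition$item_id, item_cols)
  if (length(absent)) {
    if (missing == "error") {
      stop(
        "no answers for composition item(s): ",
        paste(absent, collapse = ", "), call. = FALSE
      )
    }
    warning(
      length(absent), " composition item(s) without answers treated as",
      " 'never': ", paste(utils::head(absent, 5), collapse = ", "),
      call. = FALSE
    )
  }

  n <- nrow(responses)
  items <- composition$item_id
  codes <- matrix(0L, nrow = n, ncol = length(items),
                  dimnames = list(NULL, items))
  for (it in item_cols) {
    codes[, it] <- resolve_codes(responses[[it]], missing, item = it)
  }
  mult <- matrix(multiplier_for(as.integer(codes), scheme),
                 nrow = n, ncol = length(items))
  portions <- as.matrix(composition[, .nutrients$column])
  totals <- mult %*% portions

  liquid <- as.logical(composition$is_liquid)
  free_fluid <- if (any(liquid)) {
    as.numeric(mult[, liquid, drop = FALSE] %*%
                 composition$water_ml[liquid])
  } else {
    rep(0, n)
  }

  out <- tibble::as_tibble(as.data.frame(totals))
  names(out) <- .nutrients$column
  dplyr::bind_cols(
    tibble::tibble(participant_id = ids), out,
    tibble::tibble(free_fluid_ml = free_fluid)
  )
}

#' Daily intake for a single participant
#'
#' Convenience wrapper over [compute_cohort()] for one response.
#'
#' @param answers Named vector or list mapping `item_id` to frequency
#'   category code (0-8) or canonical label.
#' @param composition,scheme,missing As in [compute_cohort()].
#' @param participant_id Identifier used in the returned row.
#' @return One-row tibble as returned by [compute_cohort()].
#' @export
compute_daily_intake <- function(answers, composition,
                                 scheme = frequency_scheme(),
                                 participant_id = "participant",
                                 missing = c("never", "error")) {
  resp <- tibble::tibble(participant_id = participant_id)
  for (nm in names(answers)) resp[[nm]] <- answers[[nm]]
  compute_cohort(resp, composition, scheme, missing = missing)
}

#' Free-fluid intake (mL/day) per participant
#'
#' Sum of multiplier-weighted water over liquid items only. Equivalent to
#' running [compute_cohort()] on the liquid subset of the composition table
#' and taking its water column.
#'
#' @inheritParams compute_cohort
#' @return Numeric vector (mL/day), one element per participant, named by
#'   `participant_id`.
#' @export
compute_free_fluid <- function(responses, composition,
                               scheme = frequency_scheme(),
                               missing = c("never", "error")) {
  intakes <- compute_cohort(responses, composition, scheme, missing = missing)
  stats::setNames(intakes$free_fluid_ml, intakes$participant_id)
}
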
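# Small in-code fixtures used across test files.

# one composition row with zero defaults for unspecified nutrients
make_item <- function(item_id, is_liquid = FALSE, ...) {
  amounts <- list(...)
  row <- tibble::tibble(
    item_id = item_id,
    name = paste("test", item_id),
    is_liquid = is_liquid
  )
  for (col in nutrient_info()$column) {
    row[[col]] <- if (col %in% names(amounts)) amounts[[col]] else 0
  }
  row
}

# composition with one liquid (tea, 250 mL water/portion) and two solids
tiny_composition <- function() {
  dplyr::bind_rows(
    make_item("tea", is_liquid = TRUE, water_ml = 250, energy_kcal = 2,
              k_mg = 20),
    make_item("bread", protein_g = 10, carb_g = 50, energy_kcal = 260,
              water_ml = 15, na_mg = 400),
    make_item("cheese", protein_g = 4, fat_g = 9, energy_kcal = 110,
              water_ml = 10, ca_mg = 200)
  )
}

# responses where every listed participant answers every item
make_responses <- function(ids, ..., items = NULL) {
  answers <- list(...)
  resp <- tibble::tibble(participant_id = ids)
  for (nm in names(answers)) resp[[nm]] <- answers[[nm]]
  if (!is.null(items)) {
    for (it in setdiff(items, names(answers))) resp[[it]] <- 0L
  }
  resp
}

# independent brute-force accumulation oracle for daily intakes:
# explicit participant x item x nutrient loops, no matrix algebra
oracle_intakes <- function(responses, composition,
                           scheme = frequency_scheme()) {
  cols <- nutrient_info()$column
  n <- nrow(responses)
  out <- matrix(0, nrow = n, ncol = length(cols),
                dimnames = list(NULL, cols))
  free <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(composition))) {
      it <- composition$item_id[j]
      code <- if (it %in% names(responses)) responses[[it]][i] else 0L
      m <- multiplier_for(as.integer(code), scheme)
      for (col in cols) {
        out[i, col] <- out[i, col] + m * composition[[col]][j]
      }
      if (isTRUE(as.logical(composition$is_liquid[j]))) {
        free[i] <- free[i] + m * composition$water_ml[j]
      }
    }
  }
  list(totals = out, free_fluid = free)
}

# sample of size n with exactly the requested mean and sample SD,
# built by affine rescaling of a fixed base sequence
affine_sample <- function(mean, sd, n) {
  base <- sin(seq_len(n))   # fixed, non-degenerate base values
  (base - base::mean(base)) / stats::sd(base) * sd + mean
}

# intake tibble with given per-nutrient columns (others zeroed)
make_intakes <- function(n, ...) {
  vals <- list(...)
  out <- tibble::tibble(participant_id = sprintf("p%02d", seq_len(n)))
  for (col in c(nutrient_info()$column, "free_fluid_ml")) {
    out[[col]] <- if (col %in% names(vals)) vals[[col]] else rep(0, n)
  }
  out
}
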
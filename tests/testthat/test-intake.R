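test_that("daily intake handles zero, identity and mixed-frequency cases", {
  comp <- tiny_composition()
  items <- comp$item_id

  # all never -> zero vector, zero free fluid
  zero <- compute_cohort(
    make_responses("p1", items = items), comp
  )
  expect_true(all(zero[nutrient_info()$column] == 0))
  expect_equal(zero$free_fluid_ml, 0)

  # single item once per day -> that item's per-portion vector
  one <- compute_cohort(
    make_responses("p1", bread = 5L, items = items), comp
  )
  expect_equal(one$protein_g, 10)
  expect_equal(one$carb_g, 50)
  expect_equal(one$energy_kcal, 260)

  # two items at 2-4/week and 2-3/day: protein 0.45*10 + 2.5*4 = 14.5
  two <- compute_cohort(
    make_responses("p1", bread = 3L, cheese = 6L, items = items), comp
  )
  expect_equal(two$protein_g, 0.45 * 10 + 2.5 * 4)
  expect_equal(two$protein_g, 14.5)
})

test_that("free fluid counts water from liquid items only", {
  comp <- tiny_composition()
  items <- comp$item_id

  # solid-only diet -> 0 mL free fluid even though solids contain water
  solid <- compute_cohort(
    make_responses("p1", bread = 5L, cheese = 5L, items = items), comp
  )
  expect_equal(solid$free_fluid_ml, 0)
  expect_gt(solid$water_ml, 0)

  # tea 250 mL at 2-3/day -> 625 mL/day
  tea <- compute_cohort(
    make_responses("p1", tea = 6L, items = items), comp
  )
  expect_equal(tea$free_fluid_ml, 2.5 * 250)

  # mixed diet: free fluid strictly below total water
  mixed <- compute_cohort(
    make_responses("p1", tea = 5L, bread = 5L, items = items), comp
  )
  expect_lt(mixed$free_fluid_ml, mixed$water_ml)

  # free fluid equals the intake engine run on the liquid-only table
  liquid_only <- comp[comp$is_liquid, ]
  resp <- make_responses("p1", tea = 5L, bread = 5L, items = items)
  ff <- compute_free_fluid(resp, comp)
  again <- compute_cohort(resp[, c("participant_id", "tea")], liquid_only)
  expect_equal(unname(ff), again$water_ml)
})

test_that("matrix path agrees with the brute-force loop oracle", {
  scheme <- frequency_scheme()
  for (seed in 1:5) {
    set.seed(seed)
    n_items <- sample(2:5, 1)
    n <- sample(1:5, 1)
    comp <- generate_composition(seed = seed * 11, n_items = n_items,
                                 liquid_fraction = 0.4)
    resp <- tibble::tibble(participant_id = sprintf("p%d", seq_len(n)))
    for (it in comp$item_id) {
      resp[[it]] <- sample(0:8, n, replace = TRUE)
    }
    got <- compute_cohort(resp, comp, scheme)
    want <- oracle_intakes(resp, comp, scheme)
    expect_equal(
      as.matrix(got[, nutrient_info()$column]),
      want$totals, tolerance = 1e-9, ignore_attr = TRUE
    )
    expect_equal(got$free_fluid_ml, want$free_fluid, tolerance = 1e-9)
  }
})

test_that("intake is linear in portions and monotone in frequency", {
  comp <- tiny_composition()
  items <- comp$item_id
  resp <- make_responses(c("a", "b"), tea = c(5L, 2L), bread = c(3L, 7L),
                         cheese = c(1L, 0L))
  base <- compute_cohort(resp, comp)

  # scaling every per-portion vector by c scales every total by c
  scaled <- comp
  for (col in nutrient_info()$column) scaled[[col]] <- comp[[col]] * 3
  tripled <- compute_cohort(resp, scaled)
  expect_equal(
    as.matrix(tripled[, nutrient_info()$column]),
    3 * as.matrix(base[, nutrient_info()$column])
  )
  expect_equal(tripled$free_fluid_ml, 3 * base$free_fluid_ml)

  # raising one answer never decreases any component
  for (code in 0:7) {
    lo <- compute_cohort(make_responses("p", bread = code, items = items),
                         comp)
    hi <- compute_cohort(make_responses("p", bread = code + 1L,
                                        items = items), comp)
    expect_true(all(
      as.matrix(hi[, nutrient_info()$column]) >=
        as.matrix(lo[, nutrient_info()$column])
    ))
  }
})

test_that("cohort conversion preserves order, length and ids", {
  comp <- tiny_composition()
  resp <- make_responses(c("x", "y", "z"), tea = c(1L, 5L, 0L),
                         bread = c(2L, 2L, 8L), cheese = c(0L, 3L, 3L))
  out <- compute_cohort(resp, comp)
  expect_identical(out$participant_id, c("x", "y", "z"))

  perm <- resp[c(3, 1, 2), ]
  out_perm <- compute_cohort(perm, comp)
  expect_equal(out_perm, out[c(3, 1, 2), ], ignore_attr = TRUE)

  empty <- compute_cohort(resp[0, ], comp)
  expect_identical(nrow(empty), 0L)
})

test_that("schema violations are rejected with informative errors", {
  comp <- tiny_composition()
  resp <- make_responses(c("a", "a"), tea = c(1L, 2L), bread = c(0L, 0L),
                         cheese = c(0L, 0L))
  expect_error(compute_cohort(resp, comp), "duplicate participant_id")

  resp2 <- make_responses("a", tea = 1L, pizza = 3L)
  expect_error(compute_cohort(resp2, comp), "pizza")

  resp3 <- make_responses("a", tea = 12L, bread = 0L, cheese = 0L)
  expect_error(compute_cohort(resp3, comp), "invalid frequency code")
})

test_that("missing answers follow the configured policy", {
  comp <- tiny_composition()
  # absent item column: warned and treated as never
  resp <- make_responses("a", tea = 5L)
  expect_warning(out <- compute_cohort(resp, comp), "treated as")
  expect_equal(out$protein_g, 0)
  expect_error(compute_cohort(resp, comp, missing = "error"),
               "no answers")

  # NA cells likewise
  resp_na <- make_responses(c("a", "b"), tea = c(5L, NA),
                            bread = c(0L, 0L), cheese = c(0L, 0L))
  expect_warning(out2 <- compute_cohort(resp_na, comp), "missing answer")
  expect_equal(out2$free_fluid_ml, c(250, 0))
  expect_error(compute_cohort(resp_na, comp, missing = "error"),
               "missing answer")
})
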
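test_that("summarize_nutrient reproduces the closed-form t interval", {
  # frozen closed-form oracle: mean 20, sd 10, t(0.975, 2) = 4.3026527
  row <- summarize_nutrient(c(10, 20, 30))
  expect_equal(row$mean, 20)
  expect_equal(row$sd, 10)
  expect_equal(row$ci_lower, -4.8413771175, tolerance = 1e-9)
  expect_equal(row$ci_upper, 44.8413771175, tolerance = 1e-9)
  expect_equal(row$median, 20)
  expect_equal(c(row$min, row$max), c(10, 30))
})

test_that("degenerate samples yield degenerate intervals", {
  const <- summarize_nutrient(c(5, 5, 5, 5))
  expect_equal(const$sd, 0)
  expect_equal(c(const$ci_lower, const$ci_upper), c(5, 5))

  expect_warning(single <- summarize_nutrient(7), "fewer than 2")
  expect_equal(c(single$ci_lower, single$ci_upper), c(7, 7))

  expect_error(summarize_nutrient(c(1, Inf)), "finite")
})

test_that("summary statistics match direct formula evaluation on random samples", {
  for (seed in 1:8) {
    set.seed(seed)
    x <- rnorm(sample(3:20, 1), mean = 100, sd = 25)
    row <- summarize_nutrient(x)
    n <- length(x)
    half <- qt(0.975, n - 1) * sd(x) / sqrt(n)
    expect_equal(row$mean, mean(x), tolerance = 1e-9)
    expect_equal(row$sd, sd(x), tolerance = 1e-9)
    expect_equal(row$ci_lower, mean(x) - half, tolerance = 1e-9)
    expect_equal(row$ci_upper, mean(x) + half, tolerance = 1e-9)
    expect_equal(row$median, median(x), tolerance = 1e-9)
    # the t interval always contains the normal-quantile interval
    zhalf <- qnorm(0.975) * sd(x) / sqrt(n)
    expect_gt(half, zhalf)
  }
})

test_that("interval width shrinks with n at fixed SD", {
  w <- vapply(c(10, 100, 1000), function(n) {
    row <- summarize_nutrient(affine_sample(50, 10, n))
    row$ci_upper - row$ci_lower
  }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("cohort_summary covers all components plus free fluid with sane ordering", {
  comp <- generate_composition(seed = 3, n_items = 12)
  co <- generate_responses(comp, n = 20, seed = 4, calibrate = FALSE)
  intk <- compute_cohort(co$responses, co$composition)
  smry <- cohort_summary(intk)
  expect_identical(
    smry$nutrient, c(nutrient_info()$nutrient, "free_fluid")
  )
  expect_true(all(smry$min <= smry$median & smry$median <= smry$max))
  expect_true(all(smry$ci_lower <= smry$mean & smry$mean <= smry$ci_upper))
  expect_true(all(smry$sd >= 0))
})

test_that("energy shares follow the Atwater identity", {
  # hand-computed: 50 g of each macro -> (200,450,200,100)/950
  even <- energy_shares(50, 50, 50, 50)
  expect_equal(
    unname(unlist(even)),
    100 * c(200, 450, 200, 100) / 950, tolerance = 1e-12
  )
  expect_equal(round(unname(unlist(even)), 2), c(21.05, 47.37, 21.05, 10.53))

  protein_only <- energy_shares(80, 0, 0, 0)
  expect_equal(unname(unlist(protein_only)), c(100, 0, 0, 0))

  # shares sum to exactly 100 before rounding, for arbitrary intakes
  for (seed in 1:5) {
    set.seed(seed)
    g <- runif(4, 0, 300)
    expect_equal(sum(energy_shares(g[1], g[2], g[3], g[4])), 100)
  }
  expect_error(energy_shares(0, 0, 0, 0), "undefined")
})

test_that("ratio-of-means energy adjustment self-normalizes and rejects zero energy", {
  smry <- tibble::tibble(
    nutrient = c("energy", "sodium"),
    mean = c(2000, 2239)
  )
  ea <- per_1000kcal_ratio_of_means(smry)
  expect_equal(ea$per_1000kcal[ea$nutrient == "energy"], 1000)
  expect_equal(ea$per_1000kcal[ea$nutrient == "sodium"], 1119.5)
  expect_error(
    per_1000kcal_ratio_of_means(tibble::tibble(nutrient = "sodium", mean = 1)),
    "energy"
  )
})

test_that("participant-level energy adjustment matches hand arithmetic", {
  # two participants: Na 2000 mg @ 2000 kcal and 4000 mg @ 2000 kcal
  intk <- make_intakes(2, energy_kcal = c(2000, 2000),
                       na_mg = c(2000, 4000))
  ea <- per_1000kcal_participant_level(intk)
  na <- ea[ea$nutrient == "sodium", ]
  expect_equal(na$mean_per_1000kcal, 1500)
  expect_equal(na$sd_per_1000kcal, 707.1067812, tolerance = 1e-6)

  # identical participants -> zero SD
  same <- per_1000kcal_participant_level(
    make_intakes(3, energy_kcal = rep(1800, 3), p_mg = rep(900, 3))
  )
  expect_equal(same$sd_per_1000kcal[same$nutrient == "phosphorus"], 0)
  expect_equal(same$mean_per_1000kcal[same$nutrient == "phosphorus"], 500)

  # intake proportional to energy -> participant-level mean equals
  # the ratio-of-means value
  e <- c(1500, 2500, 3500)
  prop <- make_intakes(3, energy_kcal = e, k_mg = 0.9 * e)
  pl <- per_1000kcal_participant_level(prop)
  rom <- per_1000kcal_ratio_of_means(cohort_summary(prop))
  expect_equal(
    pl$mean_per_1000kcal[pl$nutrient == "potassium"],
    rom$per_1000kcal[rom$nutrient == "potassium"]
  )

  # zero-energy participants excluded with a warning
  bad <- make_intakes(3, energy_kcal = c(2000, 0, 2000),
                      na_mg = c(1000, 5, 3000))
  expect_warning(ea2 <- per_1000kcal_participant_level(bad), "excluded")
  expect_equal(unique(ea2$n_used), 2L)
})

test_that("frequency distribution conserves counts and percentages", {
  items <- c("coffee", "bread")
  n <- 50
  # 19 of 50 report coffee once daily (code 5), the rest never
  resp <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:n),
    coffee = c(rep(5L, 19), rep(0L, n - 19)),
    bread = rep(0L, n)
  )
  fd <- frequency_distribution(resp)
  coffee_daily <- fd[fd$item_id == "coffee" & fd$code == 5, ]
  expect_equal(coffee_daily$n, 19L)
  expect_equal(coffee_daily$pct, 38)

  bread_never <- fd[fd$item_id == "bread" & fd$code == 0, ]
  expect_equal(bread_never$pct, 100)

  totals <- tapply(fd$n, fd$item_id, sum)
  expect_true(all(totals == n))
  pct_sums <- tapply(fd$pct, fd$item_id, sum)
  expect_true(all(abs(pct_sums - 100) < 0.1))

  expect_error(frequency_distribution(resp[0, ]), "empty")
})
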
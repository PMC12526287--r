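# Synthetic cohort machinery. No real food-composition data are emulated:
# items are synthetic, each dominated by one "driver" nutrient so that
# per-nutrient dispersion can be calibrated independently.

# per-portion amount ranges: "high" for an item driving that nutrient,
# "bg" (background) for all other items
.portion_ranges <- list(
  water        = list(high = c(150, 300),  bg = c(1, 5)),
  energy       = list(high = c(350, 800),  bg = c(5, 30)),
  protein      = list(high = c(20, 45),    bg = c(0.2, 1.5)),
  fat          = list(high = c(25, 60),    bg = c(0.2, 1.5)),
  carbohydrate = list(high = c(60, 120),   bg = c(0.5, 4)),
  fiber        = list(high = c(5, 12),     bg = c(0.05, 0.5)),
  calcium      = list(high = c(300, 700),  bg = c(2, 10)),
  magnesium    = list(high = c(100, 220),  bg = c(1, 5)),
  phosphorus   = list(high = c(350, 750),  bg = c(5, 20)),
  potassium    = list(high = c(700, 1500), bg = c(10, 40)),
  sodium       = list(high = c(900, 2000), bg = c(10, 50))
)

#' Generate a synthetic food composition table
#'
#' Builds `n_items` synthetic FFQ items with non-negative per-portion
#' nutrient vectors. A `liquid_fraction` share of items is flagged liquid;
#' liquid items carry substantial water per portion (they are the free-fluid
#' carriers) while solids carry only traces. Each solid item is dominated by
#' one non-water nutrient (driver nutrients rotate across items) so that a
#' response cohort can shape each nutrient's distribution separately. Item
#' names are synthetic placeholders, not real foods.
#'
#' @param seed Integer seed; the table is deterministic given it.
#' @param n_items Number of items (default 55).
#' @param liquid_fraction Fraction of items flagged liquid, in \[0, 1\]
#'   (default 0.2). When positive, at least one item is liquid.
#' @return Composition tibble: `item_id`, `name`, `is_liquid`, and the 11
#'   per-portion columns of [nutrient_info()].
#' @export
#' @examples
#' generate_composition(seed = 1, n_items = 10)
generate_composition <- function(seed, n_items = 55, liquid_fraction = 0.2) {
  stopifnot(is.numeric(n_items), n_items >= 1)
  if (!is.numeric(liquid_fraction) || liquid_fraction < 0 ||
      liquid_fraction > 1) {
    stop("liquid_fraction must be in [0, 1]", call. = FALSE)
  }
  n_items <- as.integer(n_items)
  withr::with_seed(seed, {
    n_liquid <- if (liquid_fraction > 0) {
      max(1L, as.integer(round(liquid_fraction * n_items)))
    } else {
      0L
    }
    is_liquid <- c(rep(TRUE, n_liquid), rep(FALSE, n_items - n_liquid))
    solids <- which(!is_liquid)
    driver <- rep("water", n_items)
    solid_nutrients <- setdiff(.nutrients$nutrient, "water")
    if (length(solids)) {
      driver[solids] <- rep_len(solid_nutrients, length(solids))
    }
    p <- matrix(0, nrow = n_items, ncol = nrow(.nutrients),
                dimnames = list(NULL, .nutrients$nutrient))
    for (k in .nutrients$nutrient) {
      rng <- .portion_ranges[[k]]
      hi <- driver == k
      p[hi, k] <- stats::runif(sum(hi), rng$high[1], rng$high[2])
      p[!hi, k] <- stats::runif(sum(!hi), rng$bg[1], rng$bg[2])
    }
    # liquids contribute no solid-food water ambiguity: their water is the
    # "high" column above; solids keep only trace water
    out <- tibble::tibble(
      item_id = sprintf("item%02d", seq_len(n_items)),
      name = sprintf("synthetic %s source %02d", driver, seq_len(n_items)),
      is_liquid = is_liquid
    )
    for (i in seq_len(nrow(.nutrients))) {
      out[[.nutrients$column[i]]] <- p[, .nutrients$nutrient[i]]
    }
    out
  })
}

# dominant ("driver") nutrient of each item: largest per-portion amount
# relative to the column's typical high magnitude
item_drivers <- function(composition) {
  p <- as.matrix(composition[, .nutrients$column])
  scale <- vapply(.nutrients$nutrient,
                  function(k) mean(.portion_ranges[[k]]$high), numeric(1))
  rel <- sweep(p, 2, scale, "/")
  .nutrients$nutrient[apply(rel, 1, which.max)]
}

# map intended per-day frequencies to category codes 0-8 using geometric
# midpoints between adjacent multipliers as boundaries
discretize_frequency <- function(lambda, scheme = frequency_scheme()) {
  m <- unname(scheme$multipliers)
  pos <- m[m > 0]
  breaks <- c(pos[1] / 2, sqrt(pos[-length(pos)] * pos[-1]))
  as.integer(findInterval(lambda, breaks))
}

#' Generate synthetic FFQ responses calibrated to cohort intake targets
#'
#' Samples a frequency category for every participant and item so that the
#' pipeline-computed daily intakes approximate the target cohort means and
#' SDs. The generative model: each participant has a lognormal overall
#' appetite; on top of it, a lognormal per-nutrient preference governs the
#' items driven by that nutrient, with its spread calibrated iteratively so
#' the achieved coefficient of variation matches the target. Intended
#' frequencies are discretized to the nine categories. Because nine discrete
#' levels cannot hit arbitrary moments exactly, a final affine rescale of
#' the composition's per-portion columns pins the achieved cohort means to
#' the targets; SDs must then land within `sd_tol` or the calibration fails
#' with an achieved-vs-target report.
#'
#' @param composition Composition table ([generate_composition()] or same
#'   schema).
#' @param targets Tibble of per-nutrient target `mean` and `sd`
#'   ([cohort_targets()] by default). All-zero targets produce an all-"never"
#'   cohort.
#' @param n Number of participants (default 50).
#' @param seed Integer seed; responses are deterministic given it. Draws are
#'   consumed participant-by-participant, so at a fixed seed a larger cohort
#'   extends a smaller one (when `calibrate = FALSE`).
#' @param calibrate Run the iterative dispersion calibration (default TRUE).
#' @param rescale Apply the final affine rescale of composition columns
#'   (default TRUE; required for tight means).
#' @param mean_tol,sd_tol Relative tolerances on achieved means (0.10) and
#'   SDs (0.25) checked after calibration.
#' @param max_rounds Calibration rounds (default 12).
#' @param appetite_cv Coefficient of variation of the shared appetite factor
#'   (default 0.35, a typical between-person total-intake spread).
#' @return List of class `ffq_synthetic_cohort`: `responses` (tibble,
#'   `participant_id` + one column per item), `composition` (possibly
#'   rescaled), and `calibration` (per-nutrient achieved vs target report).
#' @export
generate_responses <- function(composition, targets = cohort_targets(),
                               n = 50, seed = 1, calibrate = TRUE,
                               rescale = TRUE, mean_tol = 0.10,
                               sd_tol = 0.25, max_rounds = 12,
                               appetite_cv = 0.35) {
  check_composition(composition)
  stopifnot(is.data.frame(targets),
            all(c("nutrient", "mean", "sd") %in% names(targets)))
  if (any(targets$mean < 0) || any(targets$sd < 0)) {
    stop("target means and SDs must be >= 0", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(n >= 1)
  tg <- merge(data.frame(nutrient = .nutrients$nutrient), targets,
              by = "nutrient", sort = FALSE)
  tg <- tg[match(.nutrients$nutrient, tg$nutrient), ]
  if (anyNA(tg$mean) || anyNA(tg$sd)) {
    stop("targets must cover all 11 assessed nutrients", call. = FALSE)
  }
  mu_t <- tg$mean
  sd_t <- tg$sd
  items <- composition$item_id
  j_n <- length(items)
  ids <- sprintf("p%03d", seq_len(n))

  # degenerate world: nothing is ever consumed
  if (all(mu_t == 0)) {
    resp <- tibble::tibble(participant_id = ids)
    for (it in items) resp[[it]] <- 0L
    report <- tibble::tibble(
      nutrient = .nutrients$nutrient, target_mean = 0, achieved_mean = 0,
      target_sd = 0, achieved_sd = 0, scale = 1
    )
    return(structure(
      list(responses = resp, composition = composition,
           calibration = report),
      class = "ffq_synthetic_cohort"
    ))
  }

  driver <- item_drivers(composition)
  drv_idx <- match(driver, .nutrients$nutrient)
  cv_t <- ifelse(mu_t > 0, sd_t / mu_t, 0)
  sig_a <- sqrt(log(1 + appetite_cv^2))
  sig_k <- sqrt(pmax(log(1 + cv_t^2) - sig_a^2, 0.02))
  mu_item <- NULL
  scheme <- frequency_scheme()

  simulate_codes <- function(mu_item, sig_k) {
    # one contiguous chunk of draws per participant (appetite, 11 nutrient
    # preferences, per-item noise) => prefix property in n
    z <- matrix(stats::rnorm(n * (1 + nrow(.nutrients) + j_n)),
                nrow = n, byrow = TRUE)
    s <- exp(z[, 1, drop = TRUE] * sig_a - sig_a^2 / 2)
    pref <- exp(sweep(
      z[, 1 + seq_len(nrow(.nutrients)), drop = FALSE], 2, sig_k, "*"
    ) - matrix(sig_k^2 / 2, n, nrow(.nutrients), byrow = TRUE))
    eps <- exp(0.25 * z[, -seq_len(1 + nrow(.nutrients)), drop = FALSE] -
                 0.25^2 / 2)
    lambda <- (s * pref[, drv_idx, drop = FALSE]) * eps *
      matrix(mu_item, n, j_n, byrow = TRUE)
    matrix(discretize_frequency(lambda, scheme), n, j_n)
  }

  achieved <- function(codes) {
    mult <- matrix(multiplier_for(as.integer(codes), scheme), n, j_n)
    mult %*% as.matrix(composition[, .nutrients$column])
  }

  run <- withr::with_seed(seed, {
    mu_item <- pmin(pmax(stats::rlnorm(j_n, log(0.35), 0.6), 0.02), 2.5)
    best <- NULL
    rounds <- if (calibrate) max_rounds else 1L
    for (r in seq_len(rounds)) {
      codes <- simulate_codes(mu_item, sig_k)
      intk <- achieved(codes)
      m_a <- colMeans(intk)
      s_a <- if (n > 1) apply(intk, 2, stats::sd) else rep(0, ncol(intk))
      # revive nutrients whose driver items are never consumed
      dead <- m_a <= 0 & mu_t > 0
      if (any(dead)) {
        for (k in which(dead)) mu_item[drv_idx == k] <-
            pmin(mu_item[drv_idx == k] * 3, 2.5)
      }
      cv_a <- ifelse(m_a > 0, s_a / m_a, 0)
      err <- ifelse(mu_t > 0 & sd_t > 0 & m_a > 0,
                    abs(cv_a - cv_t) / pmax(cv_t, 1e-9), 0)
      score <- max(err)
      if (is.null(best) || score < best$score) {
        best <- list(codes = codes, m = m_a, s = s_a, score = score)
      }
      if (!calibrate || (score < sd_tol / 2 && !any(dead))) break
      adj <- ifelse(cv_a > 0 & cv_t > 0, (cv_t / cv_a)^0.8, 1)
      sig_k <- pmin(pmax(sig_k * pmin(pmax(adj, 0.6), 1.8), 0.05), 1.5)
    }
    best
  })

  comp_out <- composition
  scale_k <- rep(1, nrow(.nutrients))
  if (rescale) {
    scale_k <- ifelse(mu_t == 0, 0,
                      ifelse(run$m > 0, mu_t / run$m, NA_real_))
    if (anyNA(scale_k)) {
      bad <- .nutrients$nutrient[is.na(scale_k)]
      stop(
        "calibration failure: no consumption generated for ",
        paste(bad, collapse = ", "), call. = FALSE
      )
    }
    for (i in seq_len(nrow(.nutrients))) {
      comp_out[[.nutrients$column[i]]] <-
        composition[[.nutrients$column[i]]] * scale_k[i]
    }
  }
  m_fin <- run$m * scale_k
  s_fin <- run$s * scale_k

  report <- tibble::tibble(
    nutrient = .nutrients$nutrient,
    target_mean = mu_t, achieved_mean = m_fin,
    target_sd = sd_t, achieved_sd = s_fin,
    scale = scale_k
  )
  check <- mu_t > 0
  mean_ok <- abs(m_fin - mu_t)[check] <= mean_tol * mu_t[check]
  sd_check <- check & sd_t > 0
  sd_ok <- abs(s_fin - sd_t)[sd_check] <= sd_tol * sd_t[sd_check]
  if (calibrate && (!all(mean_ok) || !all(sd_ok))) {
    msg <- paste(
      utils::capture.output(print(as.data.frame(report))), collapse = "\n"
    )
    stop(
      "calibration failed to reach target moments:\n", msg, call. = FALSE
    )
  }

  resp <- tibble::tibble(participant_id = ids)
  for (j in seq_len(j_n)) resp[[items[j]]] <- run$codes[, j]
  structure(
    list(responses = resp, composition = comp_out, calibration = report),
    class = "ffq_synthetic_cohort"
  )
}

#' Dry-weight distribution model
#'
#' @param distribution `"normal"` (truncated at > 0), `"lognormal"`, or
#'   `"empirical"` (returns `values` verbatim).
#' @param mean,sd Distribution mean and SD in kg (ignored for empirical).
#' @param n Sample size (default 70, a dialysis-unit census scale).
#' @param values Numeric vector for the empirical mode.
#' @return List of class `weight_model`.
#' @export
weight_model <- function(distribution = c("normal", "lognormal", "empirical"),
                         mean = 70, sd = 14, n = 70, values = NULL) {
  distribution <- match.arg(distribution)
  if (distribution != "empirical") {
    if (!is.finite(mean) || mean <= 0 || !is.finite(sd) || sd < 0 || n < 1) {
      stop("weight model needs mean > 0, sd >= 0, n >= 1", call. = FALSE)
    }
  } else if (is.null(values) || !length(values) || any(values <= 0)) {
    stop("empirical weight model needs positive values", call. = FALSE)
  }
  structure(
    list(distribution = distribution, mean = mean, sd = sd,
         n = as.integer(n), values = values),
    class = "weight_model"
  )
}

#' Generate a synthetic dry-weight sample
#'
#' Draws `model$n` strictly positive dry weights (kg). Normal draws are
#' truncated at zero by rejection; lognormal parameters are matched to the
#' requested mean and SD; empirical mode returns the supplied values
#' verbatim.
#'
#' @param model A [weight_model()].
#' @param seed Integer seed (deterministic output).
#' @return Numeric vector of positive weights.
#' @export
#' @examples
#' generate_weights(weight_model(mean = 70, sd = 14, n = 5), seed = 1)
generate_weights <- function(model = weight_model(), seed = 1) {
  stopifnot(inherits(model, "weight_model"))
  if (model$distribution == "empirical") {
    return(as.numeric(model$values))
  }
  withr::with_seed(seed, {
    if (model$distribution == "normal") {
      if (model$sd == 0) {
        return(rep(model$mean, model$n))
      }
      w <- stats::rnorm(model$n, model$mean, model$sd)
      while (any(w <= 0)) {
        w[w <= 0] <- stats::rnorm(sum(w <= 0), model$mean, model$sd)
      }
      w
    } else {
      if (model$sd == 0) {
        return(rep(model$mean, model$n))
      }
      cv2 <- (model$sd / model$mean)^2
      sdlog <- sqrt(log(1 + cv2))
      meanlog <- log(model$mean) - sdlog^2 / 2
      stats::rlnorm(model$n, meanlog, sdlog)
    }
  })
}
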
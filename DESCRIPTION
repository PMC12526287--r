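Package: ffqdiet
Title: Dietary Intake Estimation from Food Frequency Questionnaires in
    Hemodialysis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts food frequency questionnaire (FFQ) responses into
    estimated daily nutrient intakes and free-fluid volumes for cohorts of
    maintenance hemodialysis patients, and summarizes them the way a
    renal-nutrition assessment does: descriptive cohort tables with
    Student-t confidence intervals, Atwater macronutrient energy shares,
    energy-adjusted (per 1000 kcal) nutrient densities, classification of
    intakes against operational reference bands (deficient / adequate /
    excess), and two weight-uncertainty sensitivity analyses (deterministic
    per-kilogram scenarios over a dry-weight grid, and Monte Carlo
    resampling from an aggregate dry-weight distribution). A synthetic
    cohort generator produces composition tables, response matrices and
    weight samples with the statistical structure the analysis assumes, so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
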
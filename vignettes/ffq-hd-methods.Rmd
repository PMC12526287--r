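---
title: "Estimating and profiling dietary intake in hemodialysis cohorts from FFQ data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and profiling dietary intake in hemodialysis cohorts from FFQ data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffqdiet)
```

## The problem

Adults on maintenance hemodialysis (HD) face tightly coupled dietary
constraints: fluid, sodium, potassium and phosphorus must be restrained,
while protein (≈ 1.2 g/kg/day) and energy (≈ 35 kcal/kg/day) targets are
*higher* than for the general population because of protein-energy wasting
and dialytic amino-acid losses. A food frequency questionnaire (FFQ) is a
practical way to profile habitual intake in such a cohort, especially when
the survey must stay fully anonymous and cannot be linked to body weight or
laboratory values.

`ffqdiet` implements the complete analysis chain for this setting: FFQ
category → daily intake conversion, descriptive cohort summaries, Atwater
energy shares, energy-adjusted (per 1000 kcal) nutrient densities,
adequacy-band classification, and two sensitivity analyses that recover
per-kilogram comparisons despite the absence of individual weights.

## The intake model

Each of the FFQ's items is answered with one of nine ordered frequency
categories. Category $c$ carries a per-day multiplier $m(c)$:

| code | category | multiplier |
|-----:|----------|-----------:|
| 0 | never / less than once per month | $0$ |
| 1 | 1–3 per month | $2/30$ |
| 2 | once per week | $4.5/30$ |
| 3 | 2–4 per week | $13.5/30$ |
| 4 | 5–6 per week | $22.5/30$ |
| 5 | once per day | $1$ |
| 6 | 2–3 per day | $2.5$ |
| 7 | 4–5 per day | $4.5$ |
| 8 | more than 5 per day | $6$ |

A month is taken as 30 days; the sub-daily multipliers are stored as exact
fractions (`2/30`, not `0.067`) and converted once, so no rounding drift
accumulates over the 55-item summation. Participant $i$'s daily intake of
nutrient $k$ is

$$x_{ik} = \sum_j m(c_{ij})\, p_{jk},$$

where $p_{jk}$ is item $j$'s per-portion amount. Portion sizes are *data*
(columns of the composition table), not constants of the package: FFQ
instruments inherit their portion conventions from the parent questionnaire
and never print them per item.

**Free fluid** is the water from items flagged `is_liquid` only (beverages,
soups, milk); water in solid food is excluded because interdialytic weight
gain is driven by consumed fluids. Consequently `free_fluid ≤ water` always
holds, with equality only for liquid-only diets.

Two conventions are settled here and pinned by tests: (i) the second
category is "1–3 per month" with multiplier $2/30$ (the zero multiplier
belongs to "never or less than once per month"); (ii) missing answers are
treated as "never" with a warning by default (`missing = "error"` makes
them fatal), mirroring the field convention that a completed questionnaire
enters analysis as answered.

## Descriptive summaries

`summarize_nutrient()` reports mean, median, sample SD ($n-1$), min, max and
a two-sided Student-t 95% CI, $\bar x \pm t_{0.975,\,n-1}\, s/\sqrt n$. The
t quantile (not the normal) is deliberate: on a 50-person cohort the two
differ by ~2% of the half-width, and only the t interval reproduces
published cohort tables of this kind. With $n < 2$ the interval degenerates
to the mean with a warning.

Energy shares use Atwater factors 4/9/4/2 kcal/g for
protein/fat/carbohydrate/fiber. The denominator is the *Atwater-derived*
total $\sum_k f_k g_k$ rather than the composition-table energy column, so
the four shares sum to exactly 100 by construction; on a real table the two
denominators agree to within the rounding shown.

Energy adjustment is offered in two modes because the field uses both
without always saying which:

* **ratio of means** — $1000\,\bar x_k / \bar e$; the energy row is exactly
  1000. This is the mode that reproduces a table computed from cohort-mean
  columns.
* **participant level** — $1000\,x_{ik}/e_i$ summarized as mean ± SD across
  participants. This mode carries a dispersion estimate but its mean is
  pulled up by low-energy reporters (a ratio-of-sums vs sum-of-ratios
  effect, visible in the worked example below).

Both are emitted side by side by `run_pipeline()`; they agree exactly when
intake is proportional to energy (a pinned property test).

## Adequacy classification

`default_bands()` encodes operational descriptive bands: energy 1500–3200
kcal, protein 40–120 g, fat 45–96 g, carbohydrate 275–440 g, fiber 25–50 g,
free fluid < 700 mL (upper threshold only — a fluid "deficiency" label is
never emitted), sodium ≤ 2300 mg. Classification is inclusive at the
bounds: a value exactly on a limit is adequate. That choice is arbitrary in
the literature; it is the least-surprise convention and a test pins it.

Three electrolytes (K 2000–3000, P 800–1200, Ca 1000–1500 mg) are
individualized to serum values in modern renal guidance, so their numeric
bands here are explicitly marked `assumed = TRUE` and exist only to let
count tables be produced; the sodium *lower* bound (1500 mg) is likewise an
assumption, since only the 2.3 g/day ceiling is guideline-backed.
Magnesium has no band anywhere and is summarized but never classified.
These flags surface in every output so downstream readers cannot mistake an
assumed band for a clinical target.

## Weight-uncertainty sensitivity analyses

Anonymous FFQs cannot be linked to body weight, yet the protein and energy
guidelines are per-kg. Two complementary analyses bracket the problem:

1. **Deterministic scenarios** (`per_kg_scenarios()`): cohort mean and CI
   bounds divided by each weight on a fixed grid (default 55/65/75/85 kg).
   Division by a positive scalar preserves interval ordering, and per-kg
   values strictly decrease along the grid — both pinned as properties.

2. **Monte Carlo** (`monte_carlo_per_kg()`): weights are resampled from an
   aggregate dry-weight distribution (e.g. a 70-patient unit census). Per
   iteration, one weight is drawn with replacement *per participant*,
   per-kg intakes are formed, and the cohort median is recorded; 5000
   iteration statistics are summarized as median, 95% uncertainty interval
   (2.5/97.5 percentiles) and IQR. Because intakes and weights are unlinked
   by design, the pairing scheme is a modelling choice, not a fact: the
   per-participant draw is the default, and `pairing = "shared"` (one
   weight per iteration for the whole cohort) is available. Percentiles use
   linear interpolation between order statistics (`quantile()` type 7), and
   the draw stream is fixed by a seed (participants within iteration), so
   runs are exactly reproducible.

The degenerate case is an exact oracle: if every weight equals $w$, the MC
median equals the cohort median divided by $w$ with zero-width intervals.
For 2 participants × 2 weights the iteration-statistic distribution is
checked against exhaustive enumeration of the four equally likely
assignments.

## The synthetic cohort generator

No individual-level data ship with the package; `generate_composition()`,
`generate_responses()` and `generate_weights()` build a cohort with the
statistical structure the analysis assumes. The default *stated world* is a
50-participant cohort answering a 55-item FFQ (20% liquid items) whose
daily-intake marginals match `cohort_targets()` — e.g. energy
2696.9 ± 1392.7 kcal, protein 87.7 ± 35.3 g, sodium 3018.9 ± 1658.2 mg —
and a 70-patient weight sample, by default normal(70, 14) kg truncated at
zero, a realistic dry-weight spread for a European adult HD unit.

The generative model: each participant carries a lognormal overall appetite
(CV 0.35, a typical between-person total-intake spread) times a lognormal
per-nutrient preference applied to the items *driven* by that nutrient
(each synthetic item is dominated by one nutrient; liquids are the water
carriers). Intended frequencies are discretized to the nine categories at
the geometric midpoints between adjacent multipliers. Nine discrete levels
cannot hit arbitrary moments, so calibration proceeds in two steps: the
preference spreads are adjusted iteratively (up to 12 rounds) until the
achieved coefficients of variation approach the targets, then one affine
rescale of the composition's per-portion columns pins the cohort means
exactly. Achieved SDs must land within 25% of target (means within 10%) or
the generator fails loudly with an achieved-vs-target report. The
calibration contract is stated for the default scale (50 × 55); small
structural fixtures should pass `calibrate = FALSE`, since sample moments
of a 6-person cohort are too noisy to pin.

What a green calibration does **not** establish: the generator reproduces
marginal means and SDs only. Real FFQ data have item-level correlation
structure (food patterns), reporting biases, and heavier tails than a
lognormal appetite; inter-nutrient correlations here arise solely from the
shared appetite factor. Conclusions about classification *counts* (adequacy
tables) on synthetic cohorts therefore exercise the code path, not the
epidemiology.

All generator randomness flows from one explicit seed per call
(`withr::with_seed`), never from global state. Draws are consumed in one
contiguous chunk per participant, so at a fixed seed a larger uncalibrated
cohort extends a smaller one — a property test guards this.

## Numerical choices and degenerate inputs

* Multipliers exact rationals; intake totals are a single matrix product.
* t-based CI; `sd = 0` gives a zero-width interval; `n = 1` warns.
* `quantile(type = 7)` everywhere percentiles appear.
* Boundary values classify as adequate; threshold bands never emit the
  missing side's label; band-less nutrients yield "not classifiable" and
  are excluded from count tables with a message.
* Zero-energy participants are excluded (with a count) from
  participant-level energy adjustment; an all-zero macronutrient vector is
  a hard error for energy shares.
* The report bundle is a pure function of (inputs, config, seed); a config
  hash and the seed are logged with every bundle, and all reports are
  computed before any file is written.

## Known limitations

* Dialysis vs non-dialysis day intake differences and seasonality are not
  modelled — the FFQ instrument itself does not capture them.
* The Monte Carlo brackets weight *uncertainty*, not weight–intake
  correlation; if heavier patients eat systematically more, per-kg medians
  computed from unlinked distributions are biased toward the null.
* Operational bands for K/P/Ca are tabulation devices; individualized
  serum-guided targets cannot be recovered from intake data alone.
* The energy-adjustment modes disagree on skewed cohorts; reports should
  state which mode they quote.
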
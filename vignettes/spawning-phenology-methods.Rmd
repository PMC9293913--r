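---
title: "Methods: spawning synchrony, gametogenesis, and environmental predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spawning synchrony, gametogenesis, and environmental predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spawnsync)
```

This vignette is the package's own account of its methods: the statistics it
computes, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and the
numerical and design choices that were genuinely open.

## The synchrony model

Nightly observations record, per colony and calendar night, the number of
egg-sperm bundles released. A colony-night is a *spawn* at ≥ 10 bundles
(below that, stray bundles are ignored as non-events), a *light* spawn while
counts remain practical to tally (up to ~200 bundles), and a *heavy* spawn
above that. Both cuts are field judgements with an explicit "approximately"
attached, so `class_thresholds()` exposes them; the boundary count of
exactly 200 classifies as light, because heaviness begins strictly beyond
the cut. Classification is a pure function of count and thresholds —
flags such as `is_estimate` (visual estimates during heavy spawns) never
affect it.

The Marquis index at the daily level is

$$S_M = \sum_{t=1}^{n} \frac{d_t}{D}\, p_t, \qquad
  D = \sum_{t=1}^{n} d_t, \qquad p_t = \frac{d_t}{N},$$

with $d_t$ the (weighted) number of colonies spawning on monitored night
$t$, $N$ the colonies monitored, and $D$ the cumulative spawner-days. The
closed form $S_M = \sum_t d_t^2 / (DN)$ is what the package evaluates; the
test suite checks it exhaustively against the definition form, term by
term, over every non-negative integer series with $D \le 6$ and $N \le 4$,
and to $10^{-12}$ on randomised series.

Assumptions and conventions worth making explicit:

* **$N$ is constant per campaign.** $p_t$ divides by the number of colonies
  monitored that season, not the number seen on night $t$; campaigns report
  one $N$ per species-year.
* **Missing cells are zeros, not missing data.** Within the monitored night
  set, an absent (colony, night) record means "watched, nothing released".
  Nights outside the set were not monitored and never enter $D$. This is why
  `campaign()` carries an explicit night list rather than inferring presence
  from data.
* **Light spawns are fractional colonies.** A light spawn contributes $w$
  colonies to $d_t$ (hence to $D$), with $w$ the ratio of mean light to mean
  heavy bundle counts — the average relative gamete contribution of a light
  spawn. With `weight = "auto"`, `campaign_synchrony()` recomputes $w$ from
  the campaign's own means; a fixed override supports pooling the ratio
  across years, which is the convention when a single weight is quoted for a
  two-year study. Uniform weighting scales the index linearly
  ($S_M(w\,d) = w\,S_M(d)$), so a mostly-light season is penalised exactly in
  proportion to its relative output.
* **$D = 0$ is an error, not zero synchrony.** A season with no spawning has
  an undefined index; returning 0 would conflate "nothing happened" with
  "perfectly asynchronous".
* **Rounding is render-only.** Internal values are unrounded; the report
  helpers round half away from zero to the conventional precision (3
  decimals per-year, 2 for cross-year averages, integer percent and fold).
  A cross-year mean of 0.495 therefore renders as 0.50; where a published
  source pre-rounds its inputs it may print 0.49, and the tests accept
  either rendering for that quantity.

## Lunar annotation

Lunar age is days since a supplied reference new moon, modulo the mean
synodic month (29.530588 d). Over a two-to-three-year window this drifts by
under a day relative to a true ephemeris, which is adequate for day-level
phase labels and histograms (`lunar_day_histogram()` bins spawner-nights
into integer lunar days 0–29). The epoch is deliberately a required
configuration input rather than a built-in ephemeris: the module stays
dependency-free and testable, and any reference almanac date can be
supplied. No circular-statistics test is attached; the lunar contrast the
package reproduces is descriptive (mass near day 0 versus a roughly uniform
spread).

## Gametogenesis summaries

Developmental stage (I–IV) is an input — a morphology call made at the
microscope — never inferred from size, because the stage diameter ranges
(I ~20–70, II ~50–300, III ~200–500, IV ~300–600+ µm) overlap by design.
`validate_stage_size()` only flags records whose Feret diameter falls
outside the stage range widened by a symmetric relative slack
(`slack_fraction = 0.10` by default, absorbing the "~" in the published
ranges; stage IV has no upper bound). Size histograms use left-closed 25 µm
bins starting at 0; starting at zero rather than at the observed minimum is
a choice (the alternative is not ruled out by convention) and the bin width
is exposed.

Monthly oocyte-size comparisons square-root transform the diameters (the
usual variance stabilisation for right-skewed size data; normality is
assessed visually, not tested) and run a classical one-way ANOVA with
Tukey's HSD in the Tukey–Kramer form, since monthly sample sizes differ.
Months are labelled `"YYYY-MM"` so multi-year sampling never collides.
The implementation delegates to `stats::aov()`/`stats::TukeyHSD()`; the test
suite verifies it against an explicit sum-of-squares decomposition to
$10^{-9}$ and checks the degrees-of-freedom structure (9, 1287) for a
10-month, 1297-oocyte design.

## Reproductive-output scaling

Colony-level output is fragment output scaled by surface area:
`bundles_per_colony = bundles_per_fragment × colony_area / fragment_area`,
exact and linear in each argument (and invariant to the unit both areas are
expressed in). Defaults are a 250 cm² monitored fragment and a 10,000 cm²
(1 m²) reference colony. The *representative* bundles-per-fragment value is
the arithmetic mean rounded **up** to a reporting grid of "nice" values
(mantissas 1, 1.5, 2, 2.5, 3, 4, 5, 6, 7.5, 8 × powers of ten), so means of
64 and 395 report as 75 and 400. No simple nearest-multiple rule reproduces
that pair, so the grid is an editorial convention, flagged as such: the raw
mean is always carried alongside and the projection itself can be run on
either value.

## Environmental predictors

`monthly_climatology()` pools all available hourly values by calendar month
across years — a three-year record gives one mean SST and irradiance per
month — averaging only over hours that exist, so a station outage (e.g. two
missing autumn months in one year) simply reduces that month to the
remaining years, with a warning when a month has no data at all.

The *main spawning period* is the set of months with ≥ 30% colony
participation (inclusive at the boundary) **and** mature stage-IV gametes
present. The monthly spawn/no-spawn indicator spans all sampled months of
the histology year, with 1 exactly on the main-period months; the published
precedent leaves the exact month count behind its p-values unstated, so the
package treats the full sampled year as the series and reports $n$ with
every fit.

Each candidate predictor is fit alone: a two-parameter binomial GLM by IRLS
(up to 100 iterations, coefficient tolerance $10^{-10}$), reporting
AIC $= 2k - 2\ln L$, Nagelkerke pseudo-R²
$\left(1 - (L_0/L_1)^{2/n}\right) / \left(1 - L_0^{2/n}\right)$, and the
likelihood-ratio p against the intercept-only null ($\chi^2_1$ upper tail —
well-defined even under separation, where the statistic is $-2\ln L_0$).
**Perfect separation is reported, not repaired.** When a predictor threshold
classifies every month exactly, the MLE diverges while the likelihood climbs
toward 1; the fit iterates until $|\ln L| < 5\times10^{-3}$, sets a
`separation` flag, and the diagnostics converge on the recognisable
signature AIC → 4.00, pseudo-R² → 1.00. No Firth penalty is applied,
precisely because the unpenalised signature is the quantity of interest;
penalised variants would report different, non-comparable numbers.
Predictors are ranked by ascending AIC, ties broken by higher pseudo-R²,
then name.

## What the generators emulate — and what they do not

`gen_calendar()` simulates the two archetypes as independent per-colony
nightly Bernoulli spawning:

* **Lunar broadcaster** (default N = 10, June–July season): spawn
  probability concentrated on nights 0–3 after each new moon
  (0.70/0.45/0.20/0.10), 1% baseline elsewhere, 95% of spawns heavy, heavy
  bundle counts lognormal with median 8000. Under these defaults the
  expected index is ≈ 0.49 — the synchronous-archetype regime.
* **Aperiodic dribbler** (default N = 16, June–September): constant 8%
  nightly probability (so typically 1–3, rarely up to ~6, of 16 colonies
  active), 25% of spawns heavy capped at 3 simultaneous heavy colonies per
  night, light counts lognormal with mean 64 clamped into the light band,
  heavy counts with mean 395. Mean index ≈ 0.07 once the light weighting is
  applied — the asynchronous regime.

The 200-replicate recovery test asserts only the distributional ordering
(broadcaster mean > 0.4, dribbler mean < 0.15), not point values. Bundle
count dispersion is not published anywhere we know of, so the lognormal
CV = 0.5 is a documented assumption, not an estimate. The generators do
**not** emulate: within-colony partial spawning and repeat-spawner identity
correlations across nights, weather- or tide-driven covariance between
colonies, observer error in bundle counting, or any fertilisation/larval
dynamics. Passing tests therefore demonstrate that the pipeline recovers
structure *of this idealised kind*; they cannot certify behaviour on real
calendars with correlated colony behaviour.

`gen_gametes()` draws stages from per-month mixtures and diameters uniformly
within the drawn stage's range (stage IV capped at 700 µm so the open-ended
range stays proper); real diameter distributions within a stage are not
uniform, which matters only for tests that need conservation and mixture
recovery, not shape. `gen_env()` is an annual sinusoid plus Gaussian noise
with defaults for a subtropical embayment — SST 25.8 ± 1.9 °C peaking in
early September, so the mid-summer-to-autumn spawning months sit at or above
about 25.6 °C; irradiance 500 ± 250 peaking at the solstice — with whole
months removable to emulate a station outage. Every generator draws from a
private RNG substream derived from `(seed, purpose-tag)` and restores the
caller's RNG state, so adding one generator call never perturbs another's
output.

## Numerical choices and degenerate inputs

* Closed-form index evaluation; equality with the definition form is a
  tested invariant at $10^{-12}$.
* Classification boundaries inclusive as stated (10 spawns; 200 is light;
  participation ≥ 30% qualifies).
* `monthly_stage_frequency()` omits empty months rather than zero-filling;
  percentages sum to 100 within $10^{-9}$.
* Logistic fits refuse single-class responses and non-finite predictors;
  ANOVA refuses months with fewer than two oocytes, naming the month.
* Nagelkerke R² is clamped to [0, 1] against floating-point underflow at the
  null (the unclamped value can be $-10^{-16}$).
* Tie-breaks in predictor ranking are deterministic (AIC, then pseudo-R²,
  then name), so reports are reproducible byte-for-byte.

## Problem sizes

The test suite runs at deliberately modest scale: exhaustive index checks to
$D \le 6$, $N \le 4$; 100–200 randomised property cases; 200 seeded
replicates per archetype for the recovery check; gamete draws of $10^4$ for
mixture recovery; three simulated years of hourly environmental data. These
sizes give Monte-Carlo margins far smaller than the asserted bounds while
keeping the whole suite under a minute on one core.

## Known limitations

* Synchrony is daily and single-index; circular/vector-strength statistics
  and monthly aggregation are out of scope.
* The lunar module is a mean-synodic approximation with a user-supplied
  epoch; it is not an ephemeris.
* Logistic predictors are fitted one at a time, as in the motivating
  analysis; no multi-predictor or interaction models, and no temporal
  cross-validation.
* The reporting grid for representative bundle values is an editorial
  convention; downstream arithmetic should prefer the raw means it
  accompanies.
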
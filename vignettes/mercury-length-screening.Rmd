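---
title: "Methods: mercury-length screening, trophic magnification, and harvest risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mercury-length screening, trophic magnification, and harvest risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishhg)
```

## The problem

Fishery harvest regulations are written in terms of fish length, and tissue
mercury (Hg) rises with length within a species. Where the length at which a
species crosses a consumption screening level falls *below* the minimum legal
harvest length, anglers are restricted to exactly the fish that carry the
most Hg. `fishhg` quantifies that overlap for three widely harvested
freshwater sportfish — bluegill, black crappie, and largemouth bass — using
four linked analyses: stable-isotope trophic positioning, per-lake
biomagnification regression, log-linear Hg–length models inverted to
screening-level lengths, and covariate-adjusted correlation analysis. A
synthetic multi-lake cohort generator reproduces the statistical structure
of a stratified field survey so every stage is testable without field data.

All tissue concentrations are ppm wet weight (mg/kg fresh tissue); samples
analysed dry are converted at ingest with
`hg_ww = hg_dry * (1 - percent_moisture/100)`. Lengths are total length (TL)
in mm.

## Trophic position and biomagnification

Trophic position is estimated from nitrogen isotopes against a
primary-consumer (benthic invertebrate) baseline measured in each lake:

$$\mathrm{TP} = \frac{\delta^{15}N_{fish} - \delta^{15}N_{baseline}}{3.4} + 2,$$

with the standard 3.4 per-mil enrichment per trophic transfer and the
baseline assigned trophic level 2. The formula is affine in the fish
signature; values below 2 are permitted (they indicate baseline mismatch)
and logged.

Per lake, log10 tissue Hg is regressed on TP by ordinary least squares,
pooling largemouth bass and bluegill (the species present everywhere; black
crappie collections are typically incomplete and are excluded). The slope is
the biomagnification rate — `10^slope` is the concentration multiplier per
trophic level, so slopes of 0.61–1.0 correspond to 4–10-fold increases —
and `10^intercept` is a *relative* index of Hg at the base of the food web,
comparable across lakes but not an absolute concentration. The regression is
performed on the log10 scale: only on that scale does the published mapping
from slopes to fold-increases hold, and log-transformed tissue Hg meets the
normality and variance-homogeneity assumptions of least squares.

Slope homogeneity across lakes is tested as a nested-model F-test (ANCOVA):
`log10(Hg) ~ TP * lake` against `log10(Hg) ~ TP + lake`, with
treatment-coded lake factors. This is the standard, reproducible coding; the
p-value refers to the interaction term only.

## Hg-length regression and inverse prediction

For each lake-species cell, `log10(Hg) = a + b * TL` is fitted by least
squares; the reported p-value is the regression F-test, identical to the
slope t-test in simple regression. Only cells significant at 0.05 are
inverted (an explicit `force` override exists, used for published
coefficient tables whose significance calls are taken as given). The
screening-level length is the inverse prediction

$$L^{*}(C) = \frac{\log_{10}(C) - a}{b},$$

computed by default at the USEPA screening level (0.3 ppm), the North
Carolina level (0.4 ppm), and the USFDA action level (1.0 ppm). Numerical
conventions:

* `b <= 0`: the level is never reached with increasing length; reported as
  `not_reached` rather than a negative or infinite length.
* `L* < 0`: truncated to 0 mm and flagged; it means the fitted line is
  already above the level at any length.
* `L*` outside the observed length range: flagged `extrapolated_beyond_data`
  and rendered with a trailing `*`.
* `L*` above the species' maximum achievable size (defaults 300 mm bluegill,
  500 mm black crappie, 700 mm largemouth bass): rendered as `>cap`. When
  both flags apply, the cap rendering takes precedence — a length that no
  fish of the species can reach makes the extrapolation mark moot.

The 700 mm bass cap is a working value chosen as a round number above any
plausible largemouth bass; published caps exist only for bluegill and
crappie. It is configurable in `screening_config()`.

Thresholds are monotone in the concentration for `b > 0`, so the USEPA
length is always the shortest; every computed threshold satisfies
`a + b*L* = log10(C)` to numerical precision, which the test suite asserts
at 1e-9.

## Correlations: length, age, trophic position

Tissue Hg correlates with length, but length is itself entangled with age
(slow Hg elimination accumulates with time) and trophic position
(ontogenetic diet shifts). Per lake-species cell, the package reports the
pairwise Pearson correlation of log10 Hg with each of TL, age, and TP, and
the partial correlation with each factor controlling for the other two —
computed by the residual method (correlate the OLS residuals of each
variable on the controls; p from a t reference with n - k - 2 df). The test
suite verifies the residual method against the inverse-correlation-matrix
identity to 1e-10.

The Bonferroni family is the six correlations per cell (three pairwise plus
three partial), giving a per-test threshold of 0.05/6 = 0.00833 at family
alpha 0.05. Complete-case analysis is used within each cell; no imputation.
A cell with a constant factor is omitted with a message; a factor collinear
with its controls is omitted at the factor level.

## Harvest risk and the monitoring predictor

`percent_harvestable_exceeding()` reports the share of harvestable fish
(TL at or above the species' minimum length limit; all fish for species
without a limit) whose Hg is *strictly* above a screening level — a fish
exactly at the level is not counted, since screening levels are thresholds
for concern. The summary also classifies whether the inverse-predicted
screening length falls below the harvest limit, the configuration in which
every legal fish is predicted above the level.

The routine-monitoring predictor emulates what a state agency can do with
size-limited samples: mean (untransformed, arithmetic) Hg over bass inside
the closed 320–385 mm window — the interquartile range of lengths in
long-term agency collections — regressed across lakes on the
inverse-predicted screening length. Contaminated lakes reach levels at
shorter lengths, so fitted slopes are negative. The regression is
threshold-on-mean, matching how the predictor is used (plug in a monitoring
mean, read off a screening length, floored at 0 mm).

## The synthetic cohort generator

`generate_study()` emulates a stratified electrofishing survey: per lake and
species, fish are generated and rejection-sampled into small/medium/large
length classes (cut points 115/150 mm bluegill, 203/279 mm crappie,
355/432 mm bass) until five per class are retained. Individual fish are
built generatively:

* age: uniform on integers 1–8 years (spanning typical mean ages of these
  species, roughly 3 and 5 years for bluegill and bass);
* length: von Bertalanffy mean at age plus Gaussian noise, resampled until
  positive (defaults: L-inf 260/420/580 mm and k 0.35/0.30/0.25 per year for
  bluegill/crappie/bass, typical of southeastern US reservoirs);
* trophic position: linear in length between `tp_min` (at length 0) and
  `tp_max` (at L-inf), preserving the ordering bass > crappie > bluegill,
  plus Gaussian individual scatter `tp_noise_sd` (default 0.15 trophic
  levels, about 0.5 per mil of isotope scatter). The scatter represents diet
  variability plus analytical error; it is also what keeps TP from being an
  exact affine function of length, without which partial correlations
  controlling both TL and TP would be degenerate by construction;
* delta-15N: constructed as the exact algebraic inverse of the trophic
  position formula, so the round trip through `trophic_position()` is exact;
* log10 Hg: `baseline_log10_hg + biomag_slope * TP`, plus optional direct
  age and length effects (`hg_age_slope`, `hg_length_slope`, both default
  0 — they are the switches used to emulate age-driven versus
  length-driven accumulation), plus Gaussian residual `residual_sd`
  (default 0.1; with the default trophic scatter this places Hg-length R2
  in the mid-0.5 to low-0.9 band reported for field surveys). Hg is
  therefore lognormal and strictly positive.

The default six-lake pack spans biomagnification slopes 0.61–1.0 and
food-web baselines 3e-5 to 1.8e-3 ppm, pairing the cleanest baselines with
the steepest slopes (the pattern observed in field data), and omits black
crappie from two lakes to emulate incomplete collections.

What the generator does *not* emulate: bioenergetics or Hg elimination
kinetics, seasonal variation, sex effects on Hg (sexes are assigned at
random, independent of Hg), lake-specific growth curves, and measurement
error in length or Hg. Passing tests therefore demonstrate statistical
correctness of the estimators under the assumed structure, not field
validity of any particular lake's parameters.

## Verification problem sizes

The test suite checks estimator calibration at sizes chosen to balance
Monte-Carlo error against runtime: 500 replicate lakes (30 bass + 30
bluegill each, slope 0.8, intercept -3.2, residual sd 0.1) for slope bias
and 95% CI coverage; 1000 two-lake null replicates (15 + 15 fish per lake)
for ANCOVA type-I error at alpha 0.05; 100 random 50-point instances for
the partial-correlation identity; and exhaustive enumeration of all 256
subsets of an 8-fish population for the exceedance counting.

## Known limitations

* Inverse prediction propagates no uncertainty: no confidence interval on
  `L*` is reported (a Fieller-type interval would be the natural
  extension).
* The `+2` baseline trophic level assumes a uniformly primary-consumer
  invertebrate composite; mixed-guild baselines bias TP additively.
* The food-web baseline `10^intercept` is a long extrapolation to TP 0 and
  is meaningful only as a relative index across lakes.
* Reference coefficient tables are rounded to three significant figures,
  so thresholds re-derived from them can differ from originally computed
  values by around 1 mm; comparisons use a 2 mm allowance.
* Cells are analysed independently; no hierarchical pooling across lakes.
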
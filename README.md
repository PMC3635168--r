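# fishhg

Mercury accumulates in fish tissue, and within a species it rises with body
length — the same quantity fishery harvest regulations are written in. Where
the length at which a species crosses a consumption screening level falls
below the minimum legal harvest length, regulations restrict anglers to
exactly the fish most likely to exceed the level. `fishhg` is an R package
for quantifying that overlap in multi-lake sportfish surveys (bluegill,
black crappie, largemouth bass), aimed at fishery managers, public-health
analysts, and ecotoxicologists.

## What it computes

* **Trophic position** from nitrogen isotopes against a per-lake
  primary-consumer baseline: `TP = (δ15N_fish − δ15N_baseline)/3.4 + 2`.
* **Biomagnification** per lake: OLS of log10(Hg) on TP pooling bass and
  bluegill; the slope is the bioaccumulation rate (`10^slope` = fold
  increase per trophic level) and `10^intercept` a relative food-web
  baseline Hg index; ANCOVA tests slope homogeneity across lakes.
* **Screening-level lengths** by inverse prediction from per-cell
  regressions `log10(Hg) = a + b·TL`: `L*(C) = (log10 C − a)/b` at the
  USEPA (0.3 ppm), NC (0.4 ppm) and USFDA (1.0 ppm) levels, with
  extrapolation and species-maximum-size flags and advisory-style
  `>cap` / `*` rendering.
* **Pairwise and partial correlations** of log10(Hg) with length, age and
  trophic position (residual method, Bonferroni-adjusted at 0.05/6) to
  disentangle the direct length effect from age and diet pathways.
* **Harvest risk**: percent of harvestable fish (≥ length limit) strictly
  above a screening level, and whether the screening length falls below the
  harvest limit; plus a routine-monitoring predictor regressing screening
  lengths on mean Hg of 320–385 mm bass across lakes.
* **Synthetic cohorts**: a generator reproducing the stratified 5/5/5
  size-class survey design with von Bertalanffy growth, length-linked
  trophic position and lognormal Hg, so the full pipeline is testable
  without field data.

## Worked example

Invert a published regression (White Lake largemouth bass) to the USEPA
screening length:

```r
library(fishhg)
cfg <- screening_config()
fit <- nc_reference_fit_objects()[["white.largemouth_bass"]]
fit
#> <length_hg_fit> white / largemouth_bass: log10(Hg) = -0.659 + 0.00121 * TL, R2 0.64, p 0.001, n=15, TL 140-560 mm
invert_to_threshold(fit, 0.3, cfg, level_label = "USEPA")
#> <threshold_estimate> white / largemouth_bass at USEPA (0.3 ppm): 112.5 *
```

A 112.5 mm bass already reaches 0.3 ppm in this lake — far below the 355 mm
harvest limit, so every legal bass is predicted above the screening level
(the `*` marks prediction below the observed length range).

Simulate a six-lake survey and run the full pipeline:

```r
ds <- generate_study(default_scenarios(), seed = 1)
ds
#> <survey_dataset> 240 fish across 6 lakes
#> (15 bluegill + 15 bass per lake; crappie in 4 of 6 lakes, 5 per size class)

biomag_table(ds)
#>      lake_id  n slope slope_se intercept baseline_hg_ppm    r2  p_value
#> 1 clearwater 30 1.001   0.0442     -4.51        3.09e-05 0.948 1.50e-19
#> 2   millpond 30 0.840   0.0470     -4.35        4.51e-05 0.919 7.58e-17
#> 3 piedmont_a 30 0.899   0.0386     -3.90        1.27e-04 0.951 7.22e-20
#> 4 piedmont_b 30 0.717   0.0572     -3.40        3.94e-04 0.849 5.12e-13
#> 5  reservoir 30 0.670   0.0387     -3.06        8.72e-04 0.915 1.70e-16
#> 6 springlake 30 0.649   0.0454     -2.87        1.36e-03 0.879 2.19e-14

rep <- advisory_report(ds)   # fits, thresholds, correlations, harvest risk
subset(rep$harvest_risk, species == "largemouth_bass")[, c(1, 4, 5, 7, 8, 9)]
#>      lake_id length_limit_mm n_harvestable pct_exceeding threshold_mm    threshold_vs_limit
#> 1 clearwater             355            10            30           NA                  <NA>
#> 2   millpond             355            10             0        837.1 threshold_above_limit
#> 3 piedmont_a             355            10            90        325.1 threshold_below_limit
#> 4 piedmont_b             355            10            20           NA                  <NA>
#> 5  reservoir             355            10            50        423.1 threshold_above_limit
#> 6 springlake             355            10            90           NA                  <NA>
```

The fitted slopes recover each lake's generating biomagnification rate
(true values 1.0, 0.83, 0.9, 0.75, 0.68, 0.61) within sampling error, and
`piedmont_a` shows the high-risk configuration: bass reach the USEPA level
at 325 mm, below the 355 mm limit, and 90% of harvestable bass exceed it
(`NA` thresholds are cells whose 15-fish regression was not significant at
0.05 and is therefore not inverted).

A thin command-line wrapper with `simulate`, `fit`, `thresholds`, `biomag`,
`correlations`, `risk` and `report` subcommands is in
`inst/scripts/hg-advisory.R`.

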
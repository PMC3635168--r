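Package: fishhg
Title: Fish Tissue Mercury Screening, Trophic Position, and Harvest Risk Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mercury (Hg) accumulation in freshwater
    sportfish in the context of fishery harvest regulations and public
    health screening levels. Provides stable-isotope trophic position
    estimation from delta-15N with a primary-consumer baseline, per-lake
    biomagnification (trophic magnification) regressions with
    slope-homogeneity testing, log10(Hg)-length least-squares models
    inverted to screening-level length thresholds with extrapolation
    flagging, pairwise and partial correlation analysis disentangling
    length, age, and trophic effects, harvest-regulation risk overlap
    statistics, a routine-monitoring threshold predictor, and a synthetic
    multi-lake cohort generator emulating stratified size-class survey
    designs so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
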
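#' Trophic position from nitrogen stable isotopes
#'
#' Continuous trophic position relative to a primary-consumer invertebrate
#' baseline, using the standard 3.4 permil per-trophic-transfer nitrogen
#' fractionation:
#' `TP = (fish_d15n - baseline_d15n) / 3.4 + 2`,
#' where the `+ 2` is the trophic level of the invertebrate baseline.
#' Values below 2 (fish lighter than the baseline) are permitted but
#' reported with a message, since they usually indicate a baseline mismatch.
#'
#' @param fish_d15n Fish delta-15N, permil. Vectorised.
#' @param baseline_d15n Lake invertebrate baseline delta-15N, permil.
#' @return Numeric trophic position(s).
#' @examples
#' trophic_position(10.2, 6.8) # one trophic step above the baseline -> 3
#' @export
trophic_position <- function(fish_d15n, baseline_d15n) {
  tp <- (fish_d15n - baseline_d15n) / D15N_FRACTIONATION +
    BASELINE_TROPHIC_LEVEL
  n_neg <- sum(tp < 0, na.rm = TRUE)
  if (n_neg > 0) {
    message(sprintf("trophic_position: %d value(s) below zero; check the baseline", n_neg))
  }
  tp
}

#' Per-trophic-level Hg magnification factor
#'
#' Converts a biomagnification slope on the log10 scale into the
#' dimensionless concentration multiplier per trophic level, `10^slope`.
#' A slope of 1.0 is a ten-fold increase per trophic level.
#'
#' @param slope log10 ppm per trophic level.
#' @return Multiplier per trophic level.
#' @export
factor_per_trophic_level <- function(slope) 10^slope

# Attach trophic position to fish rows using each lake's baseline.
add_trophic_position <- function(fish, lakes) {
  baseline <- lakes$baseline_d15n_permil[match(fish$lake_id, lakes$lake_id)]
  fish$trophic_position <- suppressMessages(
    trophic_position(fish$d15n_permil, baseline)
  )
  fish
}

#' Fit a lake's biomagnification regression
#'
#' Ordinary least squares of log10 tissue Hg on trophic position for one
#' lake, combining largemouth bass and bluegill (the two species present in
#' every lake; black crappie are excluded because of incomplete
#' collections). The slope measures the rate of Hg bioaccumulation up the
#' food web; the intercept, back-transformed as `10^intercept`, is a
#' relative estimate of Hg concentration at the base of the food web.
#'
#' @param records Fish rows for one lake (tibble with `species`,
#'   `hg_ppm_ww`, `d15n_permil`).
#' @param lake One-row lake context (with `lake_id`,
#'   `baseline_d15n_permil`).
#' @param species Species pooled in the regression.
#' @return A `biomag_fit`: list with `lake_id`, `slope`, `slope_se`,
#'   `intercept`, `intercept_se`, `baseline_hg` (ppm), `r2`, `p_value`, `n`.
#' @export
fit_biomagnification <- function(records, lake,
                                 species = c("largemouth_bass", "bluegill")) {
  d <- records[records$species %in% species &
                 is.finite(records$hg_ppm_ww) & is.finite(records$d15n_permil), ]
  if (nrow(d) < 3) {
    abort_fishhg(
      sprintf("lake %s: need >= 3 fish with Hg and d15N (have %d)",
              lake$lake_id, nrow(d)),
      "fishhg_data_error"
    )
  }
  tp <- suppressMessages(trophic_position(d$d15n_permil, lake$baseline_d15n_permil))
  if (stats::sd(tp) == 0) {
    abort_fishhg(sprintf("lake %s: all trophic positions identical", lake$lake_id),
                 "fishhg_singular_error")
  }
  fit <- stats::lm(log10(d$hg_ppm_ww) ~ tp)
  s <- summary(fit)
  structure(
    list(
      lake_id = lake$lake_id,
      slope = unname(stats::coef(fit)[2]),
      slope_se = s$coefficients[2, 2],
      intercept = unname(stats::coef(fit)[1]),
      intercept_se = s$coefficients[1, 2],
      baseline_hg = 10^unname(stats::coef(fit)[1]),
      r2 = s$r.squared,
      p_value = s$coefficients[2, 4],
      n = nrow(d)
    ),
    class = "biomag_fit"
  )
}

#' Biomagnification fits for every lake in a dataset
#'
#' @param dataset A [survey_dataset()].
#' @param species Species pooled per lake (default bass + bluegill).
#' @return Tibble, one row per lake, with slope, standard error, intercept,
#'   back-transformed food-web baseline Hg (ppm), r2, p-value and n.
#' @export
biomag_table <- function(dataset, species = c("largemouth_bass", "bluegill")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  rows <- lapply(seq_len(nrow(dataset$lakes)), function(i) {
    lake <- dataset$lakes[i, ]
    f <- fit_biomagnification(
      dataset$fish[dataset$fish$lake_id == lake$lake_id, ], lake, species
    )
    tibble::tibble(
      lake_id = f$lake_id, n = f$n, slope = f$slope, slope_se = f$slope_se,
      intercept = f$intercept, baseline_hg_ppm = f$baseline_hg,
      r2 = f$r2, p_value = f$p_value
    )
  })
  do.call(rbind, rows)
}

#' Test homogeneity of biomagnification slopes across lakes
#'
#' Analysis of covariance: compares the interaction model
#' `log10(Hg) ~ TP * lake` against the parallel-slopes model
#' `log10(Hg) ~ TP + lake` with an F-test on the lake-by-TP interaction.
#' A small p-value means lakes differ in their biomagnification slopes.
#'
#' @param dataset A [survey_dataset()] covering >= 2 lakes.
#' @param species Species pooled per lake (default bass + bluegill).
#' @return List with `f_statistic`, `p_value`, `df` (numerator,
#'   denominator), and `n_lakes`.
#' @export
test_slope_homogeneity <- function(dataset,
                                   species = c("largemouth_bass", "bluegill")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  fish <- add_trophic_position(dataset$fish, dataset$lakes)
  d <- fish[fish$species %in% species &
              is.finite(fish$hg_ppm_ww) & is.finite(fish$trophic_position), ]
  lakes_present <- unique(d$lake_id)
  if (length(lakes_present) < 2) {
    abort_fishhg("slope homogeneity test requires >= 2 lakes",
                 "fishhg_data_error")
  }
  d$lake <- factor(d$lake_id)
  d$log_hg <- log10(d$hg_ppm_ww)
  full <- stats::lm(log_hg ~ trophic_position * lake, data = d)
  reduced <- stats::lm(log_hg ~ trophic_position + lake, data = d)
  a <- stats::anova(reduced, full)
  list(
    f_statistic = a$F[2],
    p_value = a$`Pr(>F)`[2],
    df = c(a$Df[2], a$Res.Df[2]),
    n_lakes = length(lakes_present)
  )
}

#' @export
print.biomag_fit <- function(x, ...) {
  cat(sprintf(
    "<biomag_fit> lake %s: slope %.3f (SE %.3f, %.1f-fold per trophic level), baseline %.2e ppm, R2 %.2f, n=%d\n",
    x$lake_id, x$slope, x$slope_se, factor_per_trophic_level(x$slope),
    x$baseline_hg, x$r2, x$n
  ))
  invisible(x)
}
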
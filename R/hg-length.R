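#' Construct a log10(Hg)-length fit object
#'
#' Container for a fitted (or published) per-lake, per-species regression
#' `log10(Hg ppm ww) = intercept_a + slope_b * TL(mm)`. Normally produced
#' by [fit_length_regression()]; the constructor is exported so published
#' coefficient tables can be used for inverse prediction directly.
#'
#' @param lake_id,species Cell identifiers.
#' @param intercept_a log10 ppm at length 0.
#' @param slope_b log10 ppm per mm TL.
#' @param r2 Coefficient of determination.
#' @param p_value Regression F-test p-value.
#' @param n Number of fish.
#' @param length_range Length-2 numeric, observed min/max TL (mm).
#' @return An object of class `length_hg_fit`.
#' @export
length_hg_fit <- function(lake_id, species, intercept_a, slope_b, r2,
                          p_value, n, length_range) {
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2],
            n >= 3)
  structure(
    list(lake_id = lake_id, species = species, intercept_a = intercept_a,
         slope_b = slope_b, r2 = r2, p_value = p_value, n = n,
         length_range = as.numeric(length_range)),
    class = "length_hg_fit"
  )
}

#' Fit the log10(Hg)-length regression for one lake-species cell
#'
#' Least-squares regression of log10 tissue Hg (ppm wet weight) on total
#' length (mm). The log10 transform is standard for tissue Hg (it meets
#' normality and variance-homogeneity assumptions); the p-value is the
#' regression F-test, identical to the slope t-test in simple regression.
#'
#' @param records Fish rows for one lake and species, with `hg_ppm_ww` and
#'   `total_length_mm`.
#' @return A [length_hg_fit()].
#' @export
fit_length_regression <- function(records) {
  d <- records[is.finite(records$hg_ppm_ww) & is.finite(records$total_length_mm), ]
  if (nrow(d) < 3) {
    abort_fishhg(sprintf("need >= 3 fish with Hg and length (have %d)", nrow(d)),
                 "fishhg_data_error")
  }
  if (stats::sd(d$total_length_mm) == 0) {
    abort_fishhg("all lengths identical: regression design is singular",
                 "fishhg_singular_error")
  }
  fit <- stats::lm(log10(hg_ppm_ww) ~ total_length_mm, data = d)
  s <- summary(fit)
  fstat <- s$fstatistic
  length_hg_fit(
    lake_id = unique(d$lake_id) %||% NA_character_,
    species = unique(d$species) %||% NA_character_,
    intercept_a = unname(stats::coef(fit)[1]),
    slope_b = unname(stats::coef(fit)[2]),
    r2 = s$r.squared,
    p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = nrow(d),
    length_range = range(d$total_length_mm)
  )
}

#' Fit Hg-length regressions for every lake-species cell
#'
#' @param dataset A [survey_dataset()].
#' @param min_n Minimum fish per cell (default 3).
#' @return Tibble, one row per cell, with coefficients, r2, p-value, n and
#'   the observed length range. A list-column `fit` holds the
#'   [length_hg_fit()] objects.
#' @export
length_fit_table <- function(dataset, min_n = 3) {
  stopifnot(inherits(dataset, "survey_dataset"))
  cells <- unique(dataset$fish[, c("lake_id", "species")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- dataset$fish$lake_id == cells$lake_id[i] &
      dataset$fish$species == cells$species[i]
    d <- dataset$fish[sel, ]
    if (sum(is.finite(d$hg_ppm_ww) & is.finite(d$total_length_mm)) < min_n) next
    f <- fit_length_regression(d)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      lake_id = cells$lake_id[i], species = cells$species[i], n = f$n,
      intercept_a = f$intercept_a, slope_b = f$slope_b, r2 = f$r2,
      p_value = f$p_value, length_min = f$length_range[1],
      length_max = f$length_range[2], fit = list(f)
    )
  }
  do.call(rbind, rows)
}

#' Invert a fitted Hg-length regression to a screening-level length
#'
#' Inverse prediction: solves `intercept_a + slope_b * TL = log10(C)` for
#' the total length at which the fitted line crosses a screening
#' concentration `C`. Only regressions significant at `sig_level` are
#' inverted (set `force = TRUE` to override). The estimate is flagged when
#' it falls outside the observed length range (`extrapolated_beyond_data`)
#' and when it exceeds the species' maximum achievable size
#' (`exceeds_max_species_size`), in which case a table rendering reports it
#' as "> cap" rather than a point estimate. A non-positive slope means the
#' level is never reached with increasing length (`not_reached`). A
#' negative solution is truncated to 0 mm and flagged.
#'
#' @param fit A [length_hg_fit()].
#' @param concentration Screening level, ppm wet weight (> 0).
#' @param config A [screening_config()] (supplies the species size cap).
#' @param level_label Label carried into the result (e.g. "USEPA").
#' @param sig_level Significance gate on the regression p-value.
#' @param force Invert even when the regression is non-significant.
#' @return An object of class `threshold_estimate`: list with
#'   `level_label`, `concentration`, `length_at_level` (mm, `NA` when not
#'   reached), and logical flags `not_reached`,
#'   `extrapolated_beyond_data`, `exceeds_max_species_size`, `truncated_at_zero`.
#' @export
invert_to_threshold <- function(fit, concentration, config = screening_config(),
                                level_label = sprintf("%.1f ppm", concentration),
                                sig_level = 0.05, force = FALSE) {
  stopifnot(inherits(fit, "length_hg_fit"), concentration > 0)
  if (!force && !(fit$p_value < sig_level)) {
    abort_fishhg(
      sprintf("regression for %s/%s is not significant (p = %.3g >= %.2f); use force = TRUE to invert anyway",
              fit$lake_id, fit$species, fit$p_value, sig_level),
      "fishhg_nonsignificant_error"
    )
  }
  cap <- config$max_species_length[[fit$species]] %||% Inf
  if (is.na(cap)) cap <- Inf
  res <- list(
    lake_id = fit$lake_id, species = fit$species,
    level_label = level_label, concentration = concentration,
    length_at_level = NA_real_, not_reached = FALSE,
    extrapolated_beyond_data = FALSE, exceeds_max_species_size = FALSE,
    truncated_at_zero = FALSE, cap = cap
  )
  if (fit$slope_b <= 0) {
    res$not_reached <- TRUE
    return(structure(res, class = "threshold_estimate"))
  }
  len <- (log10(concentration) - fit$intercept_a) / fit$slope_b
  if (len < 0) {
    res$truncated_at_zero <- TRUE
    len <- max(len, 0)
  }
  res$length_at_level <- len
  res$extrapolated_beyond_data <-
    len < fit$length_range[1] || len > fit$length_range[2]
  res$exceeds_max_species_size <- len > cap
  structure(res, class = "threshold_estimate")
}

render_threshold <- function(est) {
  if (est$not_reached) return("not reached")
  if (est$exceeds_max_species_size) return(sprintf(">%g", est$cap))
  if (est$extrapolated_beyond_data) {
    return(sprintf("%.1f *", est$length_at_level))
  }
  sprintf("%.1f", est$length_at_level)
}

#' Screening-threshold length grid across fits and levels
#'
#' Builds the advisory-style grid: one row per significant lake-species
#' regression per screening level, with the inverse-predicted length, the
#' extrapolation/cap flags, and a `rendered` column mimicking published
#' advisory tables: ">cap" when the estimate exceeds the species maximum
#' size (cap rendering takes precedence), a trailing "*" when predicted
#' beyond the observed data range. Non-significant cells are omitted.
#'
#' @param fits Tibble from [length_fit_table()] (needs the `fit`
#'   list-column), or a list of [length_hg_fit()] objects.
#' @param config A [screening_config()]; its `levels` define the grid
#'   columns.
#' @param sig_level Significance gate (default 0.05).
#' @return Tibble with one row per fit-by-level combination.
#' @export
threshold_table <- function(fits, config = screening_config(), sig_level = 0.05) {
  fit_list <- if (inherits(fits, "length_hg_fit")) list(fits)
    else if (is.data.frame(fits)) fits$fit else fits
  rows <- list()
  for (f in fit_list) {
    if (!(f$p_value < sig_level)) next
    for (j in seq_along(config$levels)) {
      est <- invert_to_threshold(f, config$levels[[j]], config,
                                 level_label = names(config$levels)[j],
                                 sig_level = sig_level)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        lake_id = f$lake_id, species = f$species,
        level = est$level_label, concentration_ppm = est$concentration,
        length_at_level_mm = est$length_at_level,
        not_reached = est$not_reached,
        extrapolated_beyond_data = est$extrapolated_beyond_data,
        exceeds_max_species_size = est$exceeds_max_species_size,
        rendered = render_threshold(est)
      )
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' @export
print.length_hg_fit <- function(x, ...) {
  cat(sprintf(
    "<length_hg_fit> %s / %s: log10(Hg) = %.3f + %.5f * TL, R2 %.2f, p %.3g, n=%d, TL %g-%g mm\n",
    x$lake_id, x$species, x$intercept_a, x$slope_b, x$r2, x$p_value, x$n,
    x$length_range[1], x$length_range[2]
  ))
  invisible(x)
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> %s / %s at %s (%g ppm): %s\n",
              x$lake_id, x$species, x$level_label, x$concentration,
              render_threshold(x)))
  invisible(x)
}
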
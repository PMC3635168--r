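#' Percent of harvestable fish exceeding a screening level
#'
#' Harvestable fish are those at or above the fishery minimum length limit
#' (species without a limit treat every fish as harvestable). The
#' exceedance percentage is the share of harvestable fish whose tissue Hg
#' is strictly above the screening level: fish exactly at the level are not
#' counted as exceeding. When a threshold estimate from
#' [invert_to_threshold()] is supplied, the summary also reports whether
#' the screening-level length falls below the harvest limit (the high-risk
#' configuration where every legal fish is predicted above the level).
#'
#' @param records Fish rows for one lake and species.
#' @param limit Minimum harvest length (mm TL) or `NA` for no limit.
#' @param level Screening level, ppm wet weight.
#' @param threshold Optional `threshold_estimate` for the same cell/level.
#' @return List with `n_harvestable`, `n_exceeding`, `pct_exceeding`
#'   (`NA` when no fish are harvestable), `limit`, `level`, and
#'   `threshold_vs_limit` (`"threshold_below_limit"`,
#'   `"threshold_above_limit"`, `"not_reached"`, or `NA` when no threshold
#'   is supplied).
#' @export
percent_harvestable_exceeding <- function(records, limit, level,
                                          threshold = NULL) {
  stopifnot(level > 0)
  d <- records[is.finite(records$hg_ppm_ww) & is.finite(records$total_length_mm), ]
  harvestable <- if (is.na(limit)) rep(TRUE, nrow(d)) else d$total_length_mm >= limit
  n_h <- sum(harvestable)
  n_e <- sum(harvestable & d$hg_ppm_ww > level)
  tvl <- NA_character_
  if (!is.null(threshold)) {
    tvl <- if (threshold$not_reached) "not_reached"
      else if (is.na(limit)) "no_limit"
      else if (threshold$length_at_level < limit) "threshold_below_limit"
      else "threshold_above_limit"
  }
  list(
    n_harvestable = n_h, n_exceeding = n_e,
    pct_exceeding = if (n_h == 0) NA_real_ else 100 * n_e / n_h,
    limit = limit, level = level, threshold_vs_limit = tvl
  )
}

#' Mean tissue Hg inside a routine-monitoring length window
#'
#' Arithmetic mean of wet-weight tissue Hg over fish whose total length
#' lies inside the closed window, emulating the restricted size range an
#' agency samples during routine monitoring (default 320-385 mm, the
#' interquartile range of lengths in long-term agency collections of
#' largemouth bass).
#'
#' @param records Fish rows for one lake and species.
#' @param window Length-2 numeric, closed window in mm TL.
#' @return Mean Hg (ppm ww), or `NA` with a message when no fish fall in
#'   the window.
#' @export
monitoring_window_mean <- function(records, window = c(320, 385)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  d <- records[is.finite(records$hg_ppm_ww) & is.finite(records$total_length_mm), ]
  inside <- d$total_length_mm >= window[1] & d$total_length_mm <= window[2]
  if (!any(inside)) {
    message(sprintf("monitoring_window_mean: no fish inside [%g, %g] mm",
                    window[1], window[2]))
    return(NA_real_)
  }
  mean(d$hg_ppm_ww[inside])
}

#' Fit the routine-monitoring threshold predictor
#'
#' Regresses the per-lake screening-level length (mm, from inverse
#' prediction) on the per-lake mean tissue Hg inside the monitoring window
#' (ppm). In contaminated systems fish reach the screening level at shorter
#' lengths, so the fitted slope is negative. The correlation `r` is
#' reported signed.
#'
#' @param means Per-lake window means, ppm.
#' @param thresholds Per-lake screening-level lengths, mm.
#' @param level_label Screening-level label carried into the result.
#' @param window Monitoring window recorded with the predictor.
#' @return An object of class `monitoring_predictor`: list with
#'   `level_label`, `intercept` (mm), `slope` (mm per ppm), `r`, `r2`,
#'   `p_value`, `n`, `window`.
#' @export
fit_threshold_predictor <- function(means, thresholds,
                                    level_label = "USEPA",
                                    window = c(320, 385)) {
  ok <- is.finite(means) & is.finite(thresholds)
  means <- means[ok]; thresholds <- thresholds[ok]
  if (length(means) < 3) {
    abort_fishhg("threshold predictor needs >= 3 lakes with both values",
                 "fishhg_data_error")
  }
  fit <- stats::lm(thresholds ~ means)
  s <- summary(fit)
  structure(
    list(
      level_label = level_label,
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      r = stats::cor(means, thresholds),
      r2 = s$r.squared,
      p_value = s$coefficients[2, 4],
      n = length(means),
      window = window
    ),
    class = "monitoring_predictor"
  )
}

#' Predict a screening-level length from a monitoring mean
#'
#' Evaluates a fitted [fit_threshold_predictor()] line at a mean tissue Hg
#' value, floored at 0 mm.
#'
#' @param predictor A `monitoring_predictor`.
#' @param mean_hg Mean tissue Hg, ppm (>= 0). Vectorised.
#' @return Predicted screening-level length(s), mm.
#' @export
evaluate_predictor <- function(predictor, mean_hg) {
  stopifnot(inherits(predictor, "monitoring_predictor"), all(mean_hg >= 0))
  pmax(predictor$intercept + predictor$slope * mean_hg, 0)
}

#' @export
print.monitoring_predictor <- function(x, ...) {
  cat(sprintf(
    "<monitoring_predictor> length at %s level = %.2f %+.2f * mean Hg (r = %.2f, p = %.3g, n = %d lakes)\n",
    x$level_label, x$intercept, x$slope, x$r, x$p_value, x$n
  ))
  invisible(x)
}
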
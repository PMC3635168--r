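#' Assemble the full advisory risk report for a survey
#'
#' Runs the whole pipeline on a dataset: per-cell Hg-length fits, the
#' screening-threshold grid, per-lake biomagnification fits with the
#' slope-homogeneity test, the pairwise/partial correlation table, harvest
#' risk summaries at a chosen screening level, and (when at least three
#' lakes have fish inside the monitoring window and a significant bass
#' threshold) the routine-monitoring threshold predictors.
#'
#' @param dataset A [survey_dataset()].
#' @param config A [screening_config()].
#' @param risk_level Label of the screening level used for harvest risk
#'   summaries (default `"USEPA"`).
#' @param sig_level Significance gate for threshold inversion.
#' @return An object of class `advisory_report`: list of tibbles
#'   (`fits`, `thresholds`, `biomag`, `slope_homogeneity`, `correlations`,
#'   `harvest_risk`, `predictors`).
#' @export
advisory_report <- function(dataset, config = screening_config(),
                            risk_level = "USEPA", sig_level = 0.05) {
  stopifnot(inherits(dataset, "survey_dataset"),
            risk_level %in% names(config$levels))
  fits <- length_fit_table(dataset)
  thresholds <- threshold_table(fits, config, sig_level = sig_level)
  biomag <- biomag_table(dataset)
  homo <- test_slope_homogeneity(dataset)
  correlations <- suppressMessages(correlation_table(dataset))
  level <- config$levels[[risk_level]]

  risk_rows <- list()
  for (i in seq_len(nrow(fits))) {
    lake <- fits$lake_id[i]; sp <- fits$species[i]
    limit <- config$length_limits[[sp]] %||% NA_real_
    thr <- NULL
    if (fits$p_value[i] < sig_level) {
      thr <- invert_to_threshold(fits$fit[[i]], level, config,
                                 level_label = risk_level,
                                 sig_level = sig_level)
    }
    d <- dataset$fish[dataset$fish$lake_id == lake & dataset$fish$species == sp, ]
    ex <- percent_harvestable_exceeding(d, limit, level, threshold = thr)
    risk_rows[[length(risk_rows) + 1L]] <- tibble::tibble(
      lake_id = lake, species = sp, level = risk_level,
      length_limit_mm = limit,
      n_harvestable = ex$n_harvestable, n_exceeding = ex$n_exceeding,
      pct_exceeding = ex$pct_exceeding,
      threshold_mm = if (is.null(thr)) NA_real_ else thr$length_at_level,
      threshold_vs_limit = ex$threshold_vs_limit
    )
  }
  harvest_risk <- do.call(rbind, risk_rows)

  predictors <- list()
  bass_fits <- fits[fits$species == "largemouth_bass", ]
  if (nrow(bass_fits) >= 3) {
    means <- vapply(bass_fits$lake_id, function(lk) {
      d <- dataset$fish[dataset$fish$lake_id == lk &
                          dataset$fish$species == "largemouth_bass", ]
      suppressMessages(monitoring_window_mean(d))
    }, numeric(1))
    for (lv in names(config$levels)) {
      thr <- vapply(seq_len(nrow(bass_fits)), function(i) {
        if (!(bass_fits$p_value[i] < sig_level)) return(NA_real_)
        est <- invert_to_threshold(bass_fits$fit[[i]], config$levels[[lv]],
                                   config, level_label = lv,
                                   sig_level = sig_level)
        if (est$not_reached) NA_real_ else est$length_at_level
      }, numeric(1))
      if (sum(is.finite(means) & is.finite(thr)) >= 3) {
        predictors[[lv]] <- fit_threshold_predictor(means, thr,
                                                    level_label = lv)
      }
    }
  }

  structure(
    list(fits = fits[, setdiff(names(fits), "fit")], thresholds = thresholds,
         biomag = biomag, slope_homogeneity = homo,
         correlations = correlations, harvest_risk = harvest_risk,
         predictors = predictors, risk_level = risk_level),
    class = "advisory_report"
  )
}

#' @export
print.advisory_report <- function(x, ...) {
  cat("== Hg-length regressions ==\n")
  print(as.data.frame(x$fits), digits = 3)
  cat("\n== Screening-level threshold lengths ==\n")
  if (!is.null(x$thresholds)) {
    print(as.data.frame(x$thresholds[, c("lake_id", "species", "level", "rendered")]))
  } else cat("(no significant regressions)\n")
  cat("\n== Biomagnification (log10 Hg ~ trophic position) ==\n")
  print(as.data.frame(x$biomag), digits = 3)
  cat(sprintf("slope homogeneity (ANCOVA): F(%d, %d) = %.2f, p = %.3g\n",
              x$slope_homogeneity$df[1], x$slope_homogeneity$df[2],
              x$slope_homogeneity$f_statistic, x$slope_homogeneity$p_value))
  cat(sprintf("\n== Harvest risk at the %s level ==\n", x$risk_level))
  print(as.data.frame(x$harvest_risk), digits = 3)
  if (length(x$predictors) > 0) {
    cat("\n== Routine-monitoring threshold predictors ==\n")
    for (p in x$predictors) print(p)
  }
  invisible(x)
}

#' Write an advisory report to delimited text files
#'
#' Writes each table of an [advisory_report()] as a tab-separated file
#' under `dir`, plus a plain-text rendering of the whole report.
#'
#' @param report An `advisory_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_advisory_report <- function(report, dir) {
  stopifnot(inherits(report, "advisory_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("fits", "thresholds", "biomag", "correlations", "harvest_risk")) {
    tab <- report[[nm]]
    if (is.null(tab)) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tab, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  txt <- file.path(dir, "report.txt")
  sink(txt); on.exit(sink(), add = TRUE)
  print(report)
  paths <- c(paths, txt)
  invisible(paths)
}
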
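#' Assemble a fish survey dataset
#'
#' A survey dataset pairs one row per sampled fish with a per-lake context
#' table carrying the invertebrate delta-15N baseline used for trophic
#' position estimation. Tissue Hg is stored in ppm wet weight (mg/kg);
#' lengths in mm total length (TL).
#'
#' @param fish Data frame with columns `lake_id`, `species`,
#'   `total_length_mm`, `hg_ppm_ww` and optionally `wet_mass_g`,
#'   `d15n_permil`, `age_yr`, `sex`.
#' @param lakes Data frame with columns `lake_id`, `name`,
#'   `baseline_d15n_permil`.
#' @return An object of class `survey_dataset`: a list with tibbles `fish`
#'   and `lakes`.
#' @export
survey_dataset <- function(fish, lakes) {
  fish <- tibble::as_tibble(fish)
  lakes <- tibble::as_tibble(lakes)
  for (col in c("wet_mass_g", "d15n_permil", "age_yr")) {
    if (!col %in% names(fish)) fish[[col]] <- NA_real_
  }
  if (!"sex" %in% names(fish)) fish$sex <- "unknown"
  fish$sex[is.na(fish$sex)] <- "unknown"
  validate_fish(fish)
  validate_lakes(lakes)
  missing_lakes <- setdiff(unique(fish$lake_id), lakes$lake_id)
  if (length(missing_lakes) > 0) {
    abort_fishhg(
      sprintf("fish reference lake_id(s) absent from lake table: %s",
              paste(missing_lakes, collapse = ", ")),
      "fishhg_validation_error"
    )
  }
  cols <- c("lake_id", "species", "total_length_mm", "wet_mass_g",
            "hg_ppm_ww", "d15n_permil", "age_yr", "sex")
  structure(list(fish = fish[, cols], lakes = lakes), class = "survey_dataset")
}

validate_fish <- function(fish) {
  req <- c("lake_id", "species", "total_length_mm", "hg_ppm_ww")
  miss <- setdiff(req, names(fish))
  if (length(miss) > 0) {
    abort_fishhg(sprintf("fish table missing column(s): %s",
                         paste(miss, collapse = ", ")),
                 "fishhg_validation_error")
  }
  assert_species(fish$species)
  bad_sex <- setdiff(unique(fish$sex), SEX_LEVELS)
  if (length(bad_sex) > 0) {
    abort_fishhg(sprintf("unknown sex label(s): %s", paste(bad_sex, collapse = ", ")),
                 "fishhg_validation_error")
  }
  bad_len <- which(!is.finite(fish$total_length_mm) | fish$total_length_mm <= 0)
  if (length(bad_len) > 0) {
    abort_fishhg(sprintf("non-positive or missing total_length_mm at row(s): %s",
                         paste(bad_len, collapse = ", ")),
                 "fishhg_validation_error")
  }
  bad_hg <- which(!is.na(fish$hg_ppm_ww) & fish$hg_ppm_ww <= 0)
  if (length(bad_hg) > 0) {
    abort_fishhg(sprintf("non-positive hg_ppm_ww at row(s): %s",
                         paste(bad_hg, collapse = ", ")),
                 "fishhg_validation_error")
  }
  bad_age <- which(!is.na(fish$age_yr) & fish$age_yr < 0)
  if (length(bad_age) > 0) {
    abort_fishhg(sprintf("negative age_yr at row(s): %s",
                         paste(bad_age, collapse = ", ")),
                 "fishhg_validation_error")
  }
  invisible(fish)
}

validate_lakes <- function(lakes) {
  req <- c("lake_id", "baseline_d15n_permil")
  miss <- setdiff(req, names(lakes))
  if (length(miss) > 0) {
    abort_fishhg(sprintf("lake table missing column(s): %s",
                         paste(miss, collapse = ", ")),
                 "fishhg_validation_error")
  }
  if (anyDuplicated(lakes$lake_id)) {
    abort_fishhg("duplicate lake_id in lake table", "fishhg_validation_error")
  }
  if (any(!is.finite(lakes$baseline_d15n_permil))) {
    abort_fishhg("baseline_d15n_permil must be finite for every lake",
                 "fishhg_validation_error")
  }
  invisible(lakes)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

read_table_checked <- function(path, numeric_cols) {
  if (!file.exists(path)) {
    abort_fishhg(sprintf("file not found: %s", path), "fishhg_io_error")
  }
  d <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                         stringsAsFactors = FALSE, colClasses = "character",
                         na.strings = c("NA", ""), quote = "\"",
                         comment.char = "")
  for (col in intersect(numeric_cols, names(d))) {
    raw <- d[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad) > 0) {
      abort_fishhg(
        sprintf("malformed numeric value in column '%s' at row(s): %s",
                col, paste(bad, collapse = ", ")),
        "fishhg_validation_error"
      )
    }
    d[[col]] <- val
  }
  tibble::as_tibble(d)
}

#' Read fish and lake survey tables
#'
#' Reads delimiter-separated text (comma or tab, auto-detected) with a
#' header row. Expected fish columns: `lake_id`, `species`,
#' `total_length_mm`, `wet_mass_g`, `hg_ppm_ww`, `d15n_permil`, `age_yr`,
#' `sex`; lake columns: `lake_id`, `name`, `baseline_d15n_permil`.
#'
#' Rows with missing optional fields (`d15n_permil`, `age_yr`, `wet_mass_g`,
#' `sex`) are retained with `NA`; operations requiring a field drop those
#' rows locally. If a dry-weight Hg column `hg_ppm_dw` is supplied together
#' with `percent_moisture` (and `hg_ppm_ww` is absent), concentrations are
#' converted to wet weight at ingest via [dry_to_wet()].
#'
#' @param fish_path Path to the fish table.
#' @param lake_path Path to the lake table.
#' @return A [survey_dataset()].
#' @export
read_survey <- function(fish_path, lake_path) {
  fish <- read_table_checked(fish_path, c(
    "total_length_mm", "wet_mass_g", "hg_ppm_ww", "hg_ppm_dw",
    "percent_moisture", "d15n_permil", "age_yr"
  ))
  if (!"hg_ppm_ww" %in% names(fish) &&
      all(c("hg_ppm_dw", "percent_moisture") %in% names(fish))) {
    fish$hg_ppm_ww <- dry_to_wet(fish$hg_ppm_dw, fish$percent_moisture)
    fish$hg_ppm_dw <- NULL
    fish$percent_moisture <- NULL
  }
  lakes <- read_table_checked(lake_path, "baseline_d15n_permil")
  survey_dataset(fish, lakes)
}

#' Write fish and lake survey tables
#'
#' Writes tab-separated text round-trippable by [read_survey()].
#'
#' @param dataset A [survey_dataset()].
#' @param fish_path,lake_path Output paths.
#' @return Invisibly, the dataset.
#' @export
write_survey <- function(dataset, fish_path, lake_path) {
  stopifnot(inherits(dataset, "survey_dataset"))
  utils::write.table(dataset$fish, fish_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  utils::write.table(dataset$lakes, lake_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(dataset)
}

#' Convert dry-weight Hg concentration to wet weight
#'
#' Tissue analysed after freeze-drying reports Hg per unit dry mass; the
#' wet-weight concentration is recovered from the sample's measured percent
#' moisture: `hg_ww = hg_dry * (1 - percent_moisture / 100)`.
#'
#' @param hg_dry Hg concentration, ppm dry weight. Vectorised.
#' @param percent_moisture Percent moisture of the fresh sample, in
#'   `[0, 100)`. Vectorised.
#' @return Hg concentration in ppm wet weight.
#' @examples
#' dry_to_wet(1.0, 80) # 0.2 ppm ww
#' @export
dry_to_wet <- function(hg_dry, percent_moisture) {
  if (any(percent_moisture < 0 | percent_moisture >= 100, na.rm = TRUE)) {
    abort_fishhg("percent_moisture must lie in [0, 100)", "fishhg_domain_error")
  }
  if (any(hg_dry < 0, na.rm = TRUE)) {
    abort_fishhg("hg_dry must be non-negative", "fishhg_domain_error")
  }
  hg_dry * (1 - percent_moisture / 100)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("<survey_dataset> %d fish across %d lakes\n",
              nrow(x$fish), nrow(x$lakes)))
  tab <- table(x$fish$lake_id, x$fish$species)
  print(tab)
  invisible(x)
}
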
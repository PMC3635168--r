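#' Published Hg-length regression coefficients for six North Carolina lakes
#'
#' Reference table of published least-squares fits of log10 tissue Hg (ppm
#' wet weight) on total length (mm) for bluegill, black crappie and
#' largemouth bass surveyed in six North Carolina lakes (Adger, Bennett's
#' Millpond, Buckhorn, Mackintosh, Waterville, White). These published
#' coefficients are inputs for inverse prediction: no raw fish data
#' accompany them, so `n` is the nominal 15-fish stratified target per cell
#' and the length range is the species-level observed range (bluegill
#' 79-239 mm, black crappie 155-376 mm, largemouth bass 140-560 mm).
#' Black crappie could not be collected in Adger or White, so those cells
#' are absent.
#'
#' @return Tibble with columns `lake_id`, `species`, `p_printed` (p-value
#'   as published), `significant` (whether threshold lengths were published
#'   for the cell), `intercept_a`, `slope_b`, `r2`, `length_min`,
#'   `length_max`, `n`.
#' @export
nc_reference_fits <- function() {
  rng <- list(bluegill = c(79, 239), black_crappie = c(155, 376),
              largemouth_bass = c(140, 560))
  rows <- list(
    list("adger",     "bluegill", "0.20",  FALSE, -1.262, 0.000975, 0.12),
    list("bennetts",  "bluegill", "0.20",  FALSE, -1.537, 0.00172,  0.12),
    list("buckhorn",  "bluegill", "<0.01", TRUE,  -1.389, 0.00211,  0.56),
    list("mackintosh","bluegill", "<0.01", TRUE,  -1.687, 0.00424,  0.61),
    list("waterville","bluegill", "<0.01", TRUE,  -1.639, 0.00335,  0.76),
    list("white",     "bluegill", "<0.01", TRUE,  -1.196, 0.00296,  0.65),
    list("bennetts",  "black_crappie", "<0.01", TRUE, -2.481, 0.00651, 0.92),
    list("buckhorn",  "black_crappie", "0.02",  TRUE, -1.744, 0.00489, 0.55),
    list("mackintosh","black_crappie", "<0.01", TRUE, -1.357, 0.00162, 0.54),
    list("waterville","black_crappie", "0.05",  TRUE, -1.816, 0.00431, 0.39),
    list("adger",     "largemouth_bass", "<0.01", TRUE, -1.258, 0.00204, 0.79),
    list("bennetts",  "largemouth_bass", "<0.01", TRUE, -1.315, 0.00191, 0.64),
    list("buckhorn",  "largemouth_bass", "<0.01", TRUE, -1.396, 0.00255, 0.77),
    list("mackintosh","largemouth_bass", "<0.01", TRUE, -2.619, 0.00530, 0.73),
    list("waterville","largemouth_bass", "<0.01", TRUE, -1.412, 0.00206, 0.84),
    list("white",     "largemouth_bass", "<0.01", TRUE, -0.659, 0.00121, 0.64)
  )
  out <- tibble::tibble(
    lake_id = vapply(rows, `[[`, character(1), 1),
    species = vapply(rows, `[[`, character(1), 2),
    p_printed = vapply(rows, `[[`, character(1), 3),
    significant = vapply(rows, `[[`, logical(1), 4),
    intercept_a = vapply(rows, `[[`, numeric(1), 5),
    slope_b = vapply(rows, `[[`, numeric(1), 6),
    r2 = vapply(rows, `[[`, numeric(1), 7)
  )
  out$length_min <- vapply(out$species, function(sp) rng[[sp]][1], numeric(1))
  out$length_max <- vapply(out$species, function(sp) rng[[sp]][2], numeric(1))
  out$n <- 15L
  out
}

#' Build inverse-prediction fit objects from the published coefficients
#'
#' Converts [nc_reference_fits()] rows into [length_hg_fit()] objects
#' ready for [invert_to_threshold()] / [threshold_table()]. The published
#' p-values "<0.01" are carried as 0.001 (an upper bound consistent with
#' the significance calls); cells published as significant at p = 0.05
#' keep that value and must be inverted with the gate they were published
#' under.
#'
#' @param only_significant Drop cells whose regressions were not published
#'   as significant (default `TRUE`).
#' @return Named list of [length_hg_fit()] objects, names `lake.species`.
#' @export
nc_reference_fit_objects <- function(only_significant = TRUE) {
  tab <- nc_reference_fits()
  if (only_significant) tab <- tab[tab$significant, ]
  p_num <- vapply(tab$p_printed, function(p) {
    if (p == "<0.01") 0.001 else as.numeric(p)
  }, numeric(1), USE.NAMES = FALSE)
  fits <- lapply(seq_len(nrow(tab)), function(i) {
    length_hg_fit(
      lake_id = tab$lake_id[i], species = tab$species[i],
      intercept_a = tab$intercept_a[i], slope_b = tab$slope_b[i],
      r2 = tab$r2[i], p_value = p_num[i], n = tab$n[i],
      length_range = c(tab$length_min[i], tab$length_max[i])
    )
  })
  names(fits) <- paste(tab$lake_id, tab$species, sep = ".")
  fits
}

#' Published screening-threshold lengths for the reference lakes
#'
#' The published advisory grid corresponding to [nc_reference_fits()]:
#' estimated lengths (mm TL) at which each significant lake-species cell
#' reaches the USEPA (0.3 ppm), NC (0.4 ppm) and USFDA (1.0 ppm) levels.
#' `length_mm` is `NA` where the published cell is a greater-than species
#' cap (">300"/">500"); `beyond_data` marks estimates published as
#' extrapolated beyond the observed length range.
#'
#' @return Tibble with columns `lake_id`, `species`, `level`, `length_mm`,
#'   `beyond_data`, `exceeds_cap`, `cap`.
#' @export
nc_reference_thresholds <- function() {
  g <- function(lake, sp, epa, nc, fda, epa_x = FALSE, nc_x = FALSE, fda_x = FALSE) {
    tibble::tibble(
      lake_id = lake, species = sp,
      level = c("USEPA", "NC", "USFDA"),
      length_mm = c(epa, nc, fda),
      beyond_data = c(epa_x, nc_x, fda_x),
      exceeds_cap = is.na(c(epa, nc, fda))
    )
  }
  out <- rbind(
    g("buckhorn",   "bluegill", NA, NA, NA),
    g("mackintosh", "bluegill", 274.9, NA, NA, epa_x = TRUE),
    g("waterville", "bluegill", NA, NA, NA),
    g("white",      "bluegill", 227.3, 269.5, NA, nc_x = TRUE),
    g("bennetts",   "black_crappie", 300.9, 320.1, 381.3, fda_x = TRUE),
    g("buckhorn",   "black_crappie", 249.8, 275.3, 356.7),
    g("mackintosh", "black_crappie", NA, NA, NA),
    g("waterville", "black_crappie", 299.9, 328.9, 421.3, fda_x = TRUE),
    g("adger",      "largemouth_bass", 361.1, 422.5, 618.0, fda_x = TRUE),
    g("bennetts",   "largemouth_bass", 414.1, 479.4, 687.5, fda_x = TRUE),
    g("buckhorn",   "largemouth_bass", 341.8, 390.8, 546.6),
    g("mackintosh", "largemouth_bass", 395.2, 418.7, 493.8),
    g("waterville", "largemouth_bass", 432.1, 492.8, 686.3, fda_x = TRUE),
    g("white",      "largemouth_bass", 112.1, 215.1, 543.4)
  )
  caps <- screening_config()$max_species_length
  out$cap <- unname(caps[out$species])
  out
}
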
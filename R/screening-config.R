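#' Screening levels, harvest length limits, and size-class layout
#'
#' Bundles the regulatory and biological constants the pipeline needs:
#' tissue-Hg screening/action levels (ppm wet weight), minimum legal harvest
#' lengths per species (mm TL), the maximum achievable length per species used
#' to cap inverse-predicted thresholds, and the small/medium/large size-class
#' cut points used by stratified surveys and the synthetic cohort generator.
#'
#' Defaults follow common North Carolina practice: screening levels USEPA
#' 0.3 ppm, NC 0.4 ppm, and the USFDA 1.0 ppm action level; length limits of
#' 355 mm for largemouth bass and 203 mm for black crappie (bluegill
#' unrestricted); species maximum sizes of 300 mm (bluegill), 500 mm (black
#' crappie) and 700 mm (largemouth bass, a configurable working value).
#'
#' @param levels Named numeric vector of screening levels, ppm wet weight.
#' @param length_limits Named list, minimum harvest length per species in mm
#'   TL, or `NA` for species without a limit.
#' @param max_species_length Named numeric vector, maximum achievable length
#'   per species (mm TL); thresholds above this render as "> cap".
#' @param size_class_bounds Named list of length-2 numeric vectors: the
#'   small/medium and medium/large cut points (mm TL) per species.
#'
#' @return An object of class `screening_config`.
#' @examples
#' cfg <- screening_config()
#' cfg$levels[["USEPA"]]
#' @export
screening_config <- function(levels = c(USEPA = 0.3, NC = 0.4, USFDA = 1.0),
                             length_limits = list(
                               largemouth_bass = 355,
                               black_crappie = 203,
                               bluegill = NA_real_
                             ),
                             max_species_length = c(
                               bluegill = 300,
                               black_crappie = 500,
                               largemouth_bass = 700
                             ),
                             size_class_bounds = list(
                               bluegill = c(115, 150),
                               black_crappie = c(203, 279),
                               largemouth_bass = c(355, 432)
                             )) {
  if (any(!is.finite(levels)) || any(levels <= 0)) {
    abort_fishhg("screening levels must be positive finite ppm values",
                 "fishhg_config_error")
  }
  assert_species(names(size_class_bounds))
  for (sp in names(size_class_bounds)) {
    b <- size_class_bounds[[sp]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      abort_fishhg(
        sprintf("size-class cut points for %s must be strictly increasing", sp),
        "fishhg_config_error"
      )
    }
  }
  structure(
    list(
      levels = levels,
      length_limits = length_limits,
      max_species_length = max_species_length,
      size_class_bounds = size_class_bounds
    ),
    class = "screening_config"
  )
}

#' Read a screening configuration from a YAML or JSON-style file
#'
#' Reads a key-value file overriding any subset of the
#' [screening_config()] defaults. Recognised top-level keys: `levels`,
#' `length_limits`, `max_species_length`, `size_class_bounds`.
#'
#' @param path Path to a YAML file.
#' @return A `screening_config` object.
#' @export
read_screening_config <- function(path) {
  if (!file.exists(path)) {
    abort_fishhg(sprintf("config file not found: %s", path), "fishhg_io_error")
  }
  raw <- yaml::read_yaml(path)
  base <- screening_config()
  args <- list()
  if (!is.null(raw$levels)) args$levels <- unlist(raw$levels)
  if (!is.null(raw$length_limits)) {
    ll <- base$length_limits
    for (sp in names(raw$length_limits)) {
      v <- raw$length_limits[[sp]]
      ll[[sp]] <- if (is.null(v) || identical(v, "none")) NA_real_ else as.numeric(v)
    }
    args$length_limits <- ll
  }
  if (!is.null(raw$max_species_length)) {
    m <- base$max_species_length
    ov <- unlist(raw$max_species_length)
    m[names(ov)] <- ov
    args$max_species_length <- m
  }
  if (!is.null(raw$size_class_bounds)) {
    b <- base$size_class_bounds
    for (sp in names(raw$size_class_bounds)) {
      b[[sp]] <- as.numeric(unlist(raw$size_class_bounds[[sp]]))
    }
    args$size_class_bounds <- b
  }
  do.call(screening_config, args)
}

#' @export
print.screening_config <- function(x, ...) {
  cat("<screening_config>\n")
  cat("  levels (ppm ww):",
      paste(sprintf("%s=%.1f", names(x$levels), x$levels), collapse = ", "), "\n")
  lim <- vapply(x$length_limits, function(v) {
    if (is.na(v)) "none" else sprintf("%.0f mm", v)
  }, character(1))
  cat("  length limits:", paste(sprintf("%s=%s", names(lim), lim), collapse = ", "), "\n")
  invisible(x)
}
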
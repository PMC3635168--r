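#' @keywords internal
"_PACKAGE"

# Species handled by the pipeline; ordering is the field's conventional
# trophic ordering (planktivore/insectivore -> facultative piscivore ->
# apex predator).
SPECIES_LEVELS <- c("bluegill", "black_crappie", "largemouth_bass")
SEX_LEVELS <- c("female", "male", "unknown")

# Nitrogen isotope fractionation per trophic transfer (permil) and the
# trophic level assigned to the primary-consumer baseline.
D15N_FRACTIONATION <- 3.4
BASELINE_TROPHIC_LEVEL <- 2

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_fishhg <- function(msg, class) {
  stop(structure(
    class = c(class, "fishhg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_species <- function(species) {
  bad <- setdiff(unique(species), SPECIES_LEVELS)
  if (length(bad) > 0) {
    abort_fishhg(
      sprintf(
        "unknown species label(s): %s (expected one of %s)",
        paste(bad, collapse = ", "), paste(SPECIES_LEVELS, collapse = ", ")
      ),
      "fishhg_validation_error"
    )
  }
  invisible(species)
}

is_finite_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
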
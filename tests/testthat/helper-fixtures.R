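# Shared fixtures and independent oracles used across test files.

# Closed-form simple-regression solution via the normal equations,
# independent of stats::lm.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  resid <- y - a - b * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  se_b <- sqrt(ss_res / (n - 2) / sxx)
  list(a = a, b = b, r2 = 1 - ss_res / ss_tot, se_b = se_b)
}

# Partial correlation via the inverse of the correlation matrix:
# r_{12.rest} = -P[1,2] / sqrt(P[1,1] * P[2,2]) with P = solve(cor(M)).
partial_cor_matrix_oracle <- function(target, x, controls) {
  m <- cbind(target, x, do.call(cbind, controls))
  p <- solve(stats::cor(m))
  -p[1, 2] / sqrt(p[1, 1] * p[2, 2])
}

# A minimal one-lake fish tibble with full control over each column.
make_fish <- function(lake_id = "l1", species = "largemouth_bass",
                      total_length_mm, hg_ppm_ww,
                      d15n_permil = NA_real_, age_yr = NA_real_,
                      sex = "unknown", wet_mass_g = NA_real_) {
  tibble::tibble(
    lake_id = lake_id, species = species,
    total_length_mm = total_length_mm, wet_mass_g = wet_mass_g,
    hg_ppm_ww = hg_ppm_ww, d15n_permil = d15n_permil,
    age_yr = age_yr, sex = sex
  )
}

make_lakes <- function(lake_id = "l1", baseline = 6) {
  tibble::tibble(lake_id = lake_id, name = lake_id,
                 baseline_d15n_permil = baseline)
}

# Scenario with known biomagnification parameters for recovery tests.
recovery_scenario <- function(slope = 0.8, intercept = -3.2, sd = 0.1,
                              lake_id = "sim", ...) {
  lake_scenario(lake_id = lake_id, baseline_log10_hg = intercept,
                biomag_slope = slope, baseline_d15n = 6,
                residual_sd = sd, ...)
}
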
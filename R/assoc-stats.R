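#' Pearson product-moment correlation with two-sided t-based p-value
#'
#' Thin wrapper around [stats::cor.test()] restricted to complete pairs,
#' returning the pieces the correlation tables need.
#'
#' @param x,y Numeric vectors of equal length; pairs with any missing value
#'   are dropped; at least 3 complete pairs required.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort_fishhg("need >= 3 complete pairs", "fishhg_data_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_fishhg("correlation undefined: zero variance", "fishhg_singular_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Partial correlation by the residual method
#'
#' Correlation between `target` and `x` after removing the linear effect of
#' the control variables from both: each is regressed on the controls by
#' ordinary least squares and the residuals are correlated. The two-sided
#' p-value uses the t reference with `n - k - 2` degrees of freedom for `k`
#' controls. With no controls this reduces exactly to [pearson()].
#'
#' @param target,x Numeric vectors.
#' @param controls List (possibly empty) of numeric control vectors.
#' @return List with `r`, `p_value`, `n`, `k` (number of controls).
#' @export
partial_correlation <- function(target, x, controls = list()) {
  if (is.numeric(controls)) controls <- list(controls)
  lens <- c(length(target), length(x), vapply(controls, length, integer(1)))
  stopifnot(length(unique(lens)) == 1L)
  ok <- is.finite(target) & is.finite(x)
  for (ctrl in controls) ok <- ok & is.finite(ctrl)
  target <- target[ok]; x <- x[ok]
  controls <- lapply(controls, `[`, ok)
  n <- length(target)
  k <- length(controls)
  if (n < k + 3) {
    abort_fishhg(sprintf("need >= %d complete cases for %d controls (have %d)",
                         k + 3, k, n),
                 "fishhg_data_error")
  }
  if (k == 0) {
    out <- pearson(target, x)
    return(list(r = out$r, p_value = out$p_value, n = out$n, k = 0L))
  }
  z <- do.call(cbind, controls)
  rt <- stats::lm.fit(cbind(1, z), target)$residuals
  rx <- stats::lm.fit(cbind(1, z), x)$residuals
  if (stats::sd(rt) < 1e-12 || stats::sd(rx) < 1e-12) {
    abort_fishhg("degenerate residuals: a variable is collinear with the controls",
                 "fishhg_singular_error")
  }
  r <- stats::cor(rt, rx)
  df <- n - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(r = r, p_value = p, n = n, k = k)
}

#' Bonferroni-adjusted per-comparison alpha
#'
#' @param family_alpha Family-wise error rate (0 < alpha < 1).
#' @param m Number of comparisons in the family (>= 1).
#' @return `family_alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 6) # 0.00833..., reported as 0.008 at 3 decimals
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  stopifnot(m >= 1, family_alpha > 0, family_alpha < 1)
  family_alpha / m
}

#' One-way analysis of variance across labelled groups
#'
#' @param values Numeric response (supply log10 Hg for tissue comparisons).
#' @param groups Group labels, same length as `values`.
#' @return List with `test = "one_way_anova"`, `f_statistic`, `p_value`,
#'   `df`, `group_labels`, `n`.
#' @export
one_way_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2) {
    abort_fishhg("need >= 2 groups", "fishhg_data_error")
  }
  if (any(table(groups) < 2)) {
    abort_fishhg("every group needs >= 2 observations", "fishhg_data_error")
  }
  a <- stats::anova(stats::lm(values ~ groups))
  list(test = "one_way_anova", f_statistic = a$`F value`[1],
       p_value = a$`Pr(>F)`[1], df = c(a$Df[1], a$Df[2]),
       group_labels = levels(groups), n = length(values))
}

#' Compare tissue Hg between sexes for one species
#'
#' Two-sided, equal-variance two-sample t-test on log10 tissue Hg, female
#' versus male; unknown-sex fish are excluded.
#'
#' @param records Fish rows for one species with `hg_ppm_ww` and `sex`.
#' @return List with `test = "two_sample_t"`, `t_statistic`, `p_value`,
#'   `df`, `n_female`, `n_male`.
#' @export
sex_comparison <- function(records) {
  d <- records[records$sex %in% c("female", "male") & is.finite(records$hg_ppm_ww), ]
  nf <- sum(d$sex == "female"); nm <- sum(d$sex == "male")
  if (nf < 2 || nm < 2) {
    abort_fishhg(sprintf("need >= 2 fish of each sex (female %d, male %d)", nf, nm),
                 "fishhg_data_error")
  }
  tt <- stats::t.test(log10(hg_ppm_ww) ~ sex, data = d, var.equal = TRUE)
  list(test = "two_sample_t", t_statistic = unname(tt$statistic),
       p_value = tt$p.value, df = unname(tt$parameter),
       n_female = nf, n_male = nm)
}

#' Pairwise and partial correlations of log10 Hg with length, age and
#' trophic position
#'
#' For every lake-species cell with enough complete cases, computes the
#' pairwise Pearson correlation of log10 tissue Hg with each of total
#' length, age, and trophic position, and the partial correlation with each
#' factor controlling for the other two. This disentangles the direct
#' length effect from the age-accumulation and diet-shift pathways: a
#' factor whose pairwise r is large but whose partial r collapses toward
#' zero acts mainly through the others. Significance is marked at the
#' Bonferroni-adjusted level `family_alpha / 6` (six correlations per
#' cell).
#'
#' @param dataset A [survey_dataset()].
#' @param min_n Minimum complete cases per cell (default 5).
#' @param family_alpha Family-wise alpha per cell (default 0.05).
#' @return Tibble, one row per cell-by-factor, with `r_pairwise`,
#'   `p_pairwise`, `r_partial`, `p_partial`, `n`, `alpha_adj`,
#'   `significant_pairwise`, `significant_partial`. Cells with a constant
#'   factor or too few cases are omitted with a message.
#' @export
correlation_table <- function(dataset, min_n = 5, family_alpha = 0.05) {
  stopifnot(inherits(dataset, "survey_dataset"))
  fish <- add_trophic_position(dataset$fish, dataset$lakes)
  cells <- unique(fish[, c("lake_id", "species")])
  factors <- c("total_length_mm", "age_yr", "trophic_position")
  alpha_adj <- bonferroni_alpha(family_alpha, 6)
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    d <- fish[fish$lake_id == cells$lake_id[i] & fish$species == cells$species[i], ]
    ok <- is.finite(d$hg_ppm_ww)
    for (f in factors) ok <- ok & is.finite(d[[f]])
    d <- d[ok, ]
    if (nrow(d) < max(min_n, 5)) {
      message(sprintf("correlation_table: %s/%s omitted (%d complete cases)",
                      cells$lake_id[i], cells$species[i], nrow(d)))
      next
    }
    if (any(vapply(d[factors], stats::sd, numeric(1)) == 0)) {
      message(sprintf("correlation_table: %s/%s omitted (constant factor)",
                      cells$lake_id[i], cells$species[i]))
      next
    }
    log_hg <- log10(d$hg_ppm_ww)
    for (f in factors) {
      others <- setdiff(factors, f)
      cell <- tryCatch({
        pw <- pearson(log_hg, d[[f]])
        pc <- partial_correlation(log_hg, d[[f]],
                                  controls = lapply(others, function(o) d[[o]]))
        list(pw = pw, pc = pc)
      }, fishhg_singular_error = function(e) {
        message(sprintf("correlation_table: %s/%s factor %s omitted (%s)",
                        cells$lake_id[i], cells$species[i], f,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(cell)) next
      pw <- cell$pw; pc <- cell$pc
      rows[[length(rows) + 1L]] <- tibble::tibble(
        lake_id = cells$lake_id[i], species = cells$species[i],
        factor = c(total_length_mm = "total_length", age_yr = "age",
                   trophic_position = "trophic_position")[[f]],
        r_pairwise = pw$r, p_pairwise = pw$p_value,
        r_partial = pc$r, p_partial = pc$p_value,
        n = pw$n, alpha_adj = alpha_adj,
        significant_pairwise = pw$p_value < alpha_adj,
        significant_partial = pc$p_value < alpha_adj
      )
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}
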
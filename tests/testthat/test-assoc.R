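test_that("pearson matches the direct product-moment formula", {
  x <- c(1, 2, 4, 7, 11)
  y <- c(0.3, 0.9, 1.2, 2.4, 3.1)
  out <- pearson(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt((5 - 2) / (1 - r_hand^2))
  expect_equal(out$p_value, 2 * stats::pt(abs(t_hand), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(out$n, 5)

  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_error(pearson(x, rep(2, 5)), class = "fishhg_singular_error")
  # incomplete pairs are dropped before everything else
  xm <- c(x, NA); ym <- c(y, 5)
  expect_equal(pearson(xm, ym)$n, 5)
})

test_that("partial correlation reduces to pearson with no controls and flags collinearity", {
  set.seed(12)
  x <- rnorm(30); y <- x + rnorm(30)
  none <- partial_correlation(y, x, controls = list())
  pw <- pearson(y, x)
  expect_equal(none$r, pw$r, tolerance = 1e-12)
  expect_equal(none$p_value, pw$p_value, tolerance = 1e-12)
  expect_error(partial_correlation(y, x, controls = list(x)),
               class = "fishhg_singular_error")
})

test_that("residual-method partial correlation equals the matrix-inverse formula", {
  set.seed(99)
  for (i in 1:20) {
    n <- 50
    z1 <- rnorm(n); z2 <- rnorm(n)
    x <- 0.5 * z1 - 0.3 * z2 + rnorm(n)
    y <- 0.4 * z1 + 0.6 * x + rnorm(n)
    got <- partial_correlation(y, x, controls = list(z1, z2))
    want <- partial_cor_matrix_oracle(y, x, list(z1, z2))
    expect_equal(got$r, want, tolerance = 1e-10)
    expect_equal(got$n, n)
    expect_equal(got$k, 2L)
  }
})

test_that("partial-correlation p-values are calibrated under the null", {
  set.seed(321)
  n_reps <- 400
  rej <- replicate(n_reps, {
    n <- 30
    z <- rnorm(n)
    x <- 0.7 * z + rnorm(n)
    y <- 0.7 * z + rnorm(n)  # y independent of x given z
    partial_correlation(y, x, controls = list(z))$p_value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("bonferroni adjustment is family alpha over m", {
  expect_equal(bonferroni_alpha(0.05, 6), 0.05 / 6)
  expect_equal(round(bonferroni_alpha(0.05, 6), 3), 0.008)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 3), 0.0167, tolerance = 1e-2)
})

test_that("one-way ANOVA matches the t-test identity and direct sums of squares", {
  g <- rep(c("a", "b"), each = 6)
  v <- c(1.2, 0.8, 1.1, 0.9, 1.3, 1.0, 1.2, 0.8, 1.1, 0.9, 1.3, 1.0)
  out <- one_way_anova(v, g)
  expect_equal(out$f_statistic, 0, tolerance = 1e-12)

  set.seed(6)
  v2 <- c(rnorm(8, 0), rnorm(8, 0.8))
  g2 <- rep(c("a", "b"), each = 8)
  out2 <- one_way_anova(v2, g2)
  tt <- stats::t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(out2$f_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(out2$p_value, tt$p.value, tolerance = 1e-9)

  # three groups against the textbook between/within decomposition
  vals <- list(a = c(1, 2, 3), b = c(2, 4, 4, 6), c = c(5, 7, 9))
  v3 <- unlist(vals)
  g3 <- rep(names(vals), lengths(vals))
  grand <- mean(v3)
  ss_b <- sum(lengths(vals) * (vapply(vals, mean, numeric(1)) - grand)^2)
  ss_w <- sum(unlist(lapply(vals, function(x) (x - mean(x))^2)))
  df_b <- 2; df_w <- length(v3) - 3
  f_hand <- (ss_b / df_b) / (ss_w / df_w)
  out3 <- one_way_anova(v3, g3)
  expect_equal(out3$f_statistic, f_hand, tolerance = 1e-10)
  expect_equal(out3$p_value, stats::pf(f_hand, df_b, df_w, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(one_way_anova(1:3, rep("a", 3)), class = "fishhg_data_error")
})

test_that("sex comparison is a two-sided t on log10 Hg and excludes unknowns", {
  hg <- c(0.2, 0.3, 0.4, 0.2, 0.3, 0.4)
  fish <- make_fish(total_length_mm = rep(300, 6), hg_ppm_ww = hg,
                    sex = rep(c("female", "male"), each = 3))
  out <- sex_comparison(fish)
  expect_equal(out$t_statistic, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1, tolerance = 1e-12)

  fish_onesex <- make_fish(total_length_mm = rep(300, 4),
                           hg_ppm_ww = c(0.2, 0.3, 0.4, 0.5),
                           sex = c("female", "female", "female", "unknown"))
  expect_error(sex_comparison(fish_onesex), class = "fishhg_data_error")

  # a one-sd mean shift at n = 50 per sex is detected nearly always
  set.seed(14)
  hits <- replicate(20, {
    f <- make_fish(total_length_mm = rep(300, 100),
                   hg_ppm_ww = 10^c(rnorm(50, -1.0, 0.2), rnorm(50, -0.8, 0.2)),
                   sex = rep(c("female", "male"), each = 50))
    sex_comparison(f)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("correlation table recovers the generative pathway of Hg accumulation", {
  lakes <- make_lakes("sim", baseline = 6)
  # Hg driven only by age: partial r with length collapses, partial r with age stays
  sc_age <- recovery_scenario(slope = 0, sd = 0.05, hg_age_slope = 0.1)
  fish_age <- generate_fish(sc_age, "largemouth_bass", 120, seed = 41)
  tab_age <- suppressMessages(correlation_table(survey_dataset(fish_age, lakes)))
  r_tl <- tab_age$r_partial[tab_age$factor == "total_length"]
  r_age <- tab_age$r_partial[tab_age$factor == "age"]
  expect_lt(abs(r_tl), 0.4)
  expect_gt(r_age, 0.6)
  expect_gt(r_age - abs(r_tl), 0.2)
  # pairwise r with length is still large (length is a proxy for age)
  expect_gt(tab_age$r_pairwise[tab_age$factor == "total_length"], 0.5)

  # direct length effect survives the controls
  sc_len <- recovery_scenario(slope = 0, sd = 0.05, hg_length_slope = 0.002)
  fish_len <- generate_fish(sc_len, "largemouth_bass", 120, seed = 42)
  tab_len <- suppressMessages(correlation_table(survey_dataset(fish_len, lakes)))
  expect_gt(tab_len$r_partial[tab_len$factor == "total_length"], 0.6)

  # a constant factor degenerates and the row is omitted with a notice
  fish_const <- fish_len
  fish_const$age_yr <- 4
  expect_message(
    tab_const <- correlation_table(survey_dataset(fish_const, lakes)),
    "omitted"
  )
  expect_false("age" %in% tab_const$factor)
})

test_that("reported correlations and p-values stay in their defining ranges", {
  ds <- generate_study(default_scenarios()[c(1, 4)], seed = 23)
  tab <- suppressMessages(correlation_table(ds))
  expect_true(all(abs(tab$r_pairwise) <= 1))
  expect_true(all(abs(tab$r_partial) <= 1))
  expect_true(all(tab$p_pairwise >= 0 & tab$p_pairwise <= 1))
  expect_true(all(tab$p_partial >= 0 & tab$p_partial <= 1))
  expect_equal(unique(tab$alpha_adj), 0.05 / 6)
})
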
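test_that("harvestable exceedance percentages follow direct counting", {
  # all ten harvestable fish above the level
  sat <- make_fish(total_length_mm = seq(360, 540, by = 20),
                   hg_ppm_ww = rep(0.5, 10))
  out <- percent_harvestable_exceeding(sat, limit = 355, level = 0.3)
  expect_equal(out$pct_exceeding, 100)
  expect_equal(out$n_harvestable, 10)

  # none above
  none <- make_fish(total_length_mm = seq(360, 540, by = 20),
                    hg_ppm_ww = rep(0.1, 10))
  expect_equal(percent_harvestable_exceeding(none, 355, 0.3)$pct_exceeding, 0)

  # 16 harvestable, 4 above -> 25%
  mix <- make_fish(species = "black_crappie",
                   total_length_mm = c(rep(180, 5), rep(250, 16)),
                   hg_ppm_ww = c(rep(0.1, 5), rep(0.5, 4), rep(0.2, 12)))
  out_mix <- percent_harvestable_exceeding(mix, 203, 0.3)
  expect_equal(out_mix$n_harvestable, 16)
  expect_equal(out_mix$pct_exceeding, 25)

  # boundary fish exactly at the level do not count as exceeding
  edge <- make_fish(total_length_mm = c(400, 420), hg_ppm_ww = c(0.3, 0.31))
  expect_equal(percent_harvestable_exceeding(edge, 355, 0.3)$pct_exceeding, 50)

  # no harvestable fish: percentage undefined, count zero
  small <- make_fish(total_length_mm = c(200, 250), hg_ppm_ww = c(0.5, 0.6))
  und <- percent_harvestable_exceeding(small, 355, 0.3)
  expect_true(is.na(und$pct_exceeding))
  expect_equal(und$n_harvestable, 0)
})

test_that("sub-limit fish never change the exceedance percentage", {
  set.seed(55)
  base <- make_fish(total_length_mm = runif(12, 360, 550),
                    hg_ppm_ww = runif(12, 0.1, 0.8))
  ref <- percent_harvestable_exceeding(base, 355, 0.3)$pct_exceeding
  for (i in 1:5) {
    extra <- make_fish(total_length_mm = runif(6, 100, 354),
                       hg_ppm_ww = runif(6, 0.1, 0.8))
    got <- percent_harvestable_exceeding(rbind(base, extra), 355, 0.3)$pct_exceeding
    expect_equal(got, ref)
  }
})

test_that("monitoring window means are closed-interval arithmetic means", {
  one <- make_fish(total_length_mm = 350, hg_ppm_ww = 0.5)
  expect_equal(monitoring_window_mean(one), 0.5)

  outside <- make_fish(total_length_mm = c(300, 400), hg_ppm_ww = c(0.2, 0.4))
  expect_message(m <- monitoring_window_mean(outside), "no fish inside")
  expect_true(is.na(m))

  three <- make_fish(total_length_mm = c(320, 350, 385),
                     hg_ppm_ww = c(0.2, 0.3, 0.4))
  expect_equal(monitoring_window_mean(three), 0.3)
})

test_that("the monitoring predictor recovers exact lines and matches the OLS oracle", {
  means <- c(0.1, 0.3, 0.5, 0.7)
  thresholds <- 600 - 800 * means  # exactly linear construction
  p <- fit_threshold_predictor(means, thresholds)
  expect_equal(p$intercept, 600, tolerance = 1e-9)
  expect_equal(p$slope, -800, tolerance = 1e-9)
  expect_equal(evaluate_predictor(p, means), thresholds, tolerance = 1e-9)
  expect_lt(p$slope, 0)  # contaminated lakes reach the level at shorter lengths
  expect_equal(p$r, -1, tolerance = 1e-9)

  set.seed(3)
  m4 <- c(0.12, 0.28, 0.44, 0.61)
  t4 <- 620 - 850 * m4 + rnorm(4, 0, 15)
  p4 <- fit_threshold_predictor(m4, t4)
  o <- ols_oracle(m4, t4)
  expect_equal(p4$intercept, o$a, tolerance = 1e-10)
  expect_equal(p4$slope, o$b, tolerance = 1e-10)
  expect_equal(p4$r2, o$r2, tolerance = 1e-10)
  expect_equal(p4$r, sign(o$b) * sqrt(o$r2), tolerance = 1e-10)

  expect_error(fit_threshold_predictor(c(0.1, 0.2), c(500, 400)),
               class = "fishhg_data_error")
})

test_that("published predictor coefficients evaluate to the expected lengths", {
  usepa <- structure(list(level_label = "USEPA", intercept = 619.09,
                          slope = -869.24, r = -0.91, r2 = 0.83,
                          p_value = 0.01, n = 6, window = c(320, 385)),
                     class = "monitoring_predictor")
  expect_equal(evaluate_predictor(usepa, 0), 619.09)
  expect_equal(evaluate_predictor(usepa, 0.42), 254.0, tolerance = 1e-3)
  usfda <- structure(list(level_label = "USFDA", intercept = 767.01,
                          slope = -456.47, r = -0.83, r2 = 0.69,
                          p_value = 0.03, n = 6, window = c(320, 385)),
                     class = "monitoring_predictor")
  expect_equal(evaluate_predictor(usfda, 0.42), 575.3, tolerance = 1e-3)
  # floor at zero for extreme contamination
  expect_equal(evaluate_predictor(usepa, 2), 0)
})

test_that("threshold versus harvest limit classification matches the published cases", {
  cfg <- screening_config()
  fits <- nc_reference_fit_objects()
  fish <- make_fish(total_length_mm = c(360, 400, 450),
                    hg_ppm_ww = c(0.5, 0.6, 0.7))

  thr_white <- invert_to_threshold(fits[["white.largemouth_bass"]], 0.3, cfg)
  out_white <- percent_harvestable_exceeding(fish, 355, 0.3, threshold = thr_white)
  expect_equal(out_white$threshold_vs_limit, "threshold_below_limit")

  thr_benn <- invert_to_threshold(fits[["bennetts.largemouth_bass"]], 0.3, cfg)
  out_benn <- percent_harvestable_exceeding(fish, 355, 0.3, threshold = thr_benn)
  expect_equal(out_benn$threshold_vs_limit, "threshold_above_limit")
})

test_that("the advisory report assembles all pipeline stages coherently", {
  ds <- generate_study(default_scenarios(), seed = 19)
  rep <- suppressMessages(advisory_report(ds))
  expect_s3_class(rep, "advisory_report")
  expect_equal(nrow(rep$biomag), 6)
  expect_true(all(c("lake_id", "species", "rendered") %in% names(rep$thresholds)))
  # bluegill have no length limit: every fish is harvestable
  bg <- rep$harvest_risk[rep$harvest_risk$species == "bluegill", ]
  expect_true(all(is.na(bg$length_limit_mm)))
  expect_true(all(bg$n_harvestable == 15))
  expect_true(all(rep$harvest_risk$pct_exceeding >= 0 &
                    rep$harvest_risk$pct_exceeding <= 100, na.rm = TRUE))
  # writing produces the delimited tables plus the text rendering
  dir <- withr::local_tempdir()
  paths <- write_advisory_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.txt")))
  expect_true(file.exists(file.path(dir, "fits.tsv")))
})
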
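# Optical redox ratio: conventions, calibration, aggregation,
# interpretation.

test_that("ORR conventions obey symmetry, boundaries, and the complement
          identity", {
  n <- matrix(100, 8L, 8L)
  pair_eq <- channel_pair(n, n)
  ox <- compute_orr(pair_eq, "oxidized", prefilter = 1L, postfilter = 1L)
  expect_true(all(ox$orr_image == 0.5))
  pair0 <- channel_pair(n, matrix(0, 8L, 8L))
  expect_true(all(compute_orr(pair0, "oxidized", 1L, 1L)$orr_image == 0))
  expect_true(all(compute_orr(pair0, "reduced", 1L, 1L)$orr_image == 1))
  # random nonnegative images: oxidized + reduced = 1 exactly, ORR in
  # [0,1], zero-total pixels masked not NaN
  set.seed(4)
  a <- matrix(rpois(400, 30), 20L); b <- matrix(rpois(400, 10), 20L)
  a[1L, 1L] <- 0; b[1L, 1L] <- 0
  pr <- channel_pair(a, b)
  oxi <- compute_orr(pr, "oxidized", 1L, 1L)$orr_image
  red <- compute_orr(pr, "reduced", 1L, 1L)$orr_image
  expect_true(all(oxi[!is.na(oxi)] >= 0 & oxi[!is.na(oxi)] <= 1))
  expect_identical(oxi + red, matrix(ifelse(is.na(oxi), NA_real_, 1),
                                     20L, 20L))
  expect_true(is.na(oxi[1L, 1L]))
})

test_that("solution-standard calibration is an identity for unit
          standards and exactly gain-invariant", {
  set.seed(9)
  nad <- matrix(rpois(256, 200), 16L)
  fad <- matrix(rpois(256, 120), 16L)
  pair <- channel_pair(nad, fad)
  unit <- function(ch) solution_frame(ch, 1, dim = c(16L, 16L))
  cal <- calibrate_channels(pair, unit("nadph"), unit("fad"))
  expect_equal(cal$nadph, nad + 0)
  expect_true(cal$calibrated)
  # joint gain applied to sample and standard cancels to 1e-12
  std_n <- solution_frame("nadph", 500, dim = c(16L, 16L), seed = 1)
  std_f <- solution_frame("fad", 500, dim = c(16L, 16L), seed = 2)
  base <- compute_orr(calibrate_channels(pair, std_n, std_f),
                      prefilter = 1L, postfilter = 1L)$orr_image
  for (k in c(0.25, 3, 17)) {
    pair_k <- channel_pair(nad, fad * k)
    std_fk <- std_f
    std_fk$intensity_image <- std_f$intensity_image * k
    scaled <- compute_orr(calibrate_channels(pair_k, std_n, std_fk),
                          prefilter = 1L, postfilter = 1L)$orr_image
    expect_equal(scaled, base, tolerance = 1e-12)
  }
  expect_error(
    calibrate_channels(pair, solution_frame("nadph", 0, dim = c(4L, 4L)),
                       unit("fad")),
    "zero mean")
})

test_that("calibration collapses acquisition-setting differences that
          separate uncalibrated ORR distributions", {
  p <- biexp_from_f2(0.5)
  scene <- cell_scene(matrix(1L, 20L, 20L), list("1" = p),
                      photons = 800, intensity_nadph = 800,
                      intensity_fad = 400)
  # same sample imaged under two instrument settings (FAD gain differs 3x)
  run1 <- simulate_channel_pair(scene, c(nadph = 1, fad = 1), seed = 11)
  run2 <- simulate_channel_pair(scene, c(nadph = 1, fad = 3), seed = 12)
  orr_of <- function(run, calibrate) {
    pair <- run$pair
    if (calibrate) {
      pair <- calibrate_channels(pair, run$nadh_standard,
                                 run$fad_standard)
    }
    res <- compute_orr(pair, prefilter = 1L, postfilter = 1L)
    res$orr_image[!is.na(res$orr_image)]
  }
  raw_gap <- abs(mean(orr_of(run1, FALSE)) - mean(orr_of(run2, FALSE)))
  cal_gap <- abs(mean(orr_of(run1, TRUE)) - mean(orr_of(run2, TRUE)))
  expect_gt(raw_gap, 0.15)
  expect_lt(cal_gap, 0.02)
  ks <- suppressWarnings(
    stats::ks.test(orr_of(run1, TRUE), orr_of(run2, TRUE))$statistic)
  expect_lt(unname(ks), 0.15)
})

test_that("region aggregation: both averaging modes, brute-force oracle,
          and bounds", {
  # uniform region: the two modes agree exactly
  n <- matrix(60, 6L, 6L); f <- matrix(20, 6L, 6L)
  mask <- matrix(1L, 6L, 6L)
  pair <- channel_pair(n, f, mask = mask)
  tbl <- aggregate_orr(compute_orr(pair, prefilter = 1L,
                                   postfilter = 1L))
  expect_equal(tbl$orr_ratio_of_means, tbl$orr_mean_of_ratios,
               tolerance = 1e-12)
  # three-pixel brute force: (NADH, FAD) = (90,10), (10,90), (99,1)
  nad <- matrix(c(90, 10, 99), 1L); fad <- matrix(c(10, 90, 1), 1L)
  pr <- channel_pair(nad, fad, mask = matrix(1L, 1L, 3L))
  t3 <- aggregate_orr(compute_orr(pr, prefilter = 1L, postfilter = 1L))
  rom_oracle <- sum(fad) / (sum(nad) + sum(fad))            # 101/300
  mor_oracle <- mean(fad / (nad + fad))
  expect_equal(t3$orr_ratio_of_means, rom_oracle, tolerance = 1e-12)
  expect_equal(t3$orr_mean_of_ratios, mor_oracle, tolerance = 1e-12)
  # mean_of_ratios is bounded by the pixelwise extremes
  expect_gte(t3$orr_mean_of_ratios, min(fad / (nad + fad)))
  expect_lte(t3$orr_mean_of_ratios, max(fad / (nad + fad)))
  # a region fully below threshold is absent, with a warning
  mask2 <- matrix(c(1L, 2L, 1L), 1L)  # region 2 = the dim (10, 90) pixel
  pr2 <- channel_pair(nad, fad, mask = mask2)
  expect_warning(
    t2 <- aggregate_orr(compute_orr(pr2, prefilter = 1L, postfilter = 1L,
                                    min_intensity = 50)),
    "region 2")
  expect_false(2L %in% t2$region_id)
})

test_that("raising the intensity threshold never adds pixels", {
  set.seed(13)
  pair <- channel_pair(matrix(rpois(400, 50), 20L),
                       matrix(rpois(400, 30), 20L))
  prev <- Inf
  for (thr in c(0, 30, 50, 80)) {
    n_ok <- sum(compute_orr(pair, prefilter = 1L, postfilter = 1L,
                            min_intensity = thr)$mask)
    expect_lte(n_ok, prev)
    prev <- n_ok
  }
})

test_that("metric-change interpretation reproduces the pathway table", {
  up_ox <- interpret_metric_change("orr_oxidized", "up")
  expect_setequal(up_ox$pathway,
                  c("ETC activity", "glutaminolysis", "ETC uncoupling"))
  down_ox <- interpret_metric_change("orr_oxidized", "down")
  expect_setequal(down_ox$pathway,
                  c("glycolysis", "fatty acid oxidation",
                    "fatty acid synthesis",
                    "TCA relative to ETC activity"))
  up_bf <- interpret_metric_change("bound_fraction_or_tau_m", "up")
  expect_true("fatty acid synthesis" %in% up_bf$pathway)
  expect_false("glycolysis" %in% up_bf$pathway)
  # reduced convention mirrors oxidized
  up_red <- interpret_metric_change("orr_reduced", "up")
  expect_setequal(up_red$pathway, down_ox$pathway)
  expect_true(all(grepl("transient", up_ox$caveat)))
})
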
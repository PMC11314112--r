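test_that("curve features find peaks and inflections of simple shapes", {
  # symmetric triangle of 9 composites peaks at its centre
  tri <- c(0, 1, 2, 3, 4, 3, 2, 1, 0)
  f <- curve_features(tri)
  expect_false(f$skip)
  expect_equal(f$peak_index, 5)

  # constant curve: no inflections, first-index tie break for the peak
  fc <- curve_features(rep(1.3, 10))
  expect_equal(fc$peak_index, 1)
  expect_length(fc$inflection_indices, 0)

  # all-nodata or short curves are skipped, not errors
  expect_true(curve_features(rep(NA_real_, 10))$skip)
  expect_true(curve_features(c(NA, 1, 2, 3, 4, NA, NA, NA, NA, NA))$skip)

  # interior nodata is interpolated away
  fi <- curve_features(c(0, 1, 2, NA, 4, 3, 2, 1, 0))
  expect_false(fi$skip)
  expect_equal(fi$peak_index, 5)
})

test_that("a noiseless generator wheat curve shows the double feature", {
  cfg <- synth_config(n_rows = 4, n_cols = 4, wheat_fraction = 1,
                      cropland_fraction = 1, noise_sd = 0, seed = 3)
  lc <- make_lai_cube(cfg, 2005)
  curve <- lc$cube[, 1, 1]
  f <- curve_features(curve)
  w <- phenology_windows()

  expect_gte(f$peak_value, w$lai_max_threshold)
  expect_true(f$peak_index >= w$spring[1] && f$peak_index <= w$spring[2])
  # inflection clusters on both sides of the peak: autumn onset + senescence
  expect_true(any(f$inflection_indices < f$peak_index &
                  f$inflection_indices <= w$autumn[2]))
  expect_true(any(f$inflection_indices > f$peak_index))
  # senescence: back near zero by harvest
  expect_lt(f$final_value, w$lai_sow_max * f$peak_value)
  expect_equal(classify_pixel(f, w), 1L)

  # a constant-low pixel fails the LAI-max threshold clause
  expect_equal(classify_pixel(curve_features(rep(0.15, 16)), w), 0L)
})

test_that("noiseless classification recovers the truth mask exactly", {
  cfg <- synth_config(noise_sd = 0, seed = 101)
  lc <- make_lai_cube(cfg, 2010)
  mask <- classify_cube(lc$cube, phenology_windows())
  expect_identical(as.integer(mask), as.integer(lc$truth))
})

test_that("classification stays accurate under default LAI noise", {
  cfg <- synth_config(seed = 101)   # noise_sd 0.15
  lc <- make_lai_cube(cfg, 2010)
  mask <- classify_cube(lc$cube, phenology_windows())
  sc <- mask_scores(mask, lc$truth)
  expect_gte(sc$precision, 0.95)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$accuracy, 0.95)
})

test_that("raising the LAI-max threshold never adds wheat pixels", {
  cfg <- synth_config(n_rows = 20, n_cols = 20, seed = 8)
  lc <- make_lai_cube(cfg, 2003)
  counts <- vapply(c(0.5, 1, 2, 3, 4, 5), function(thr) {
    m <- classify_cube(lc$cube, phenology_windows(lai_max_threshold = thr))
    sum(m == 1, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cropland masking is correct, idempotent and shape-checked", {
  set.seed(21)
  mask <- matrix(rbinom(100, 1, 0.5), 10, 10)
  ones <- matrix(1L, 10, 10)
  zeros <- matrix(0L, 10, 10)
  expect_identical(apply_cropland_mask(mask, ones), mask)
  expect_true(all(apply_cropland_mask(mask, zeros) == 0))

  checker <- matrix(rep_len(c(1L, 0L), 100), 10, 10)
  m2 <- apply_cropland_mask(mask, checker)
  # brute-force pixel loop recount
  expected <- 0
  for (i in 1:10) for (j in 1:10) {
    if (mask[i, j] == 1 && checker[i, j] == 1) expected <- expected + 1
  }
  expect_equal(sum(m2 == 1), expected)
  expect_identical(apply_cropland_mask(m2, checker), m2)

  expect_error(apply_cropland_mask(mask, matrix(1L, 5, 5)), "mismatch")
  m_t <- mask; attr(m_t, "transform") <- c(0, 250, 0, 0, 0, -250)
  c_t <- checker; attr(c_t, "transform") <- c(0, 500, 0, 0, 0, -500)
  expect_error(apply_cropland_mask(m_t, c_t), "transform")
})

test_that("planting area converts pixel counts to thousand hectares", {
  expect_equal(planting_area(matrix(0L, 10, 10), 6.25), 0)
  m <- matrix(0L, 20, 20); m[1:160] <- 1L
  expect_equal(planting_area(m, 6.25), 1.0)
  expect_equal(planting_area(matrix(1L, 100, 100), 6.25), 62.5)
  expect_error(planting_area(m, 0), "positive")
})

test_that("frequency maps count presence per interval and difference them", {
  base <- matrix(0L, 4, 4)
  seasons <- 2000:2009
  masks <- lapply(seasons, function(y) base)
  names(masks) <- seasons
  # pixel (1,1): present all five seasons of interval 1, none of interval 2
  # pixel (2,2): 2 seasons in interval 1, 4 in interval 2
  for (y in as.character(2000:2004)) masks[[y]][1, 1] <- 1L
  for (y in as.character(2000:2001)) masks[[y]][2, 2] <- 1L
  for (y in as.character(2005:2008)) masks[[y]][2, 2] <- 1L
  fm <- frequency_map(masks, intervals = 2)
  expect_equal(fm$frequency[["2000-2004"]][1, 1], 5)
  expect_equal(fm$frequency[["2005-2009"]][1, 1], 0)
  expect_equal(fm$change[[1]][1, 1], -5)
  expect_equal(fm$change[[1]][2, 2], 2)

  # random masks: per-pixel frequency equals an independent recount
  set.seed(4)
  rmasks <- lapply(seasons, function(y) matrix(rbinom(16, 1, 0.5), 4, 4))
  names(rmasks) <- seasons
  fm2 <- frequency_map(rmasks, intervals = 2)
  for (i in 1:4) for (j in 1:4) {
    recount <- sum(vapply(as.character(2000:2004),
                          function(y) rmasks[[y]][i, j], numeric(1)))
    expect_equal(fm2$frequency[["2000-2004"]][i, j], recount)
  }

  expect_error(frequency_map(rmasks, intervals = 3), "equal intervals")
  expect_error(frequency_map(rmasks, intervals = list(2000:2004, 2005:2008)),
               "outside")
})
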
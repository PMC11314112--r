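test_that("config validation catches bad parameters", {
  expect_error(synth_config(n_composites = 4), "n_composites")
  expect_error(synth_config(wheat_fraction = 1.2), "wheat_fraction")
  expect_error(synth_config(noise_sd = -0.1), "noise_sd")
  expect_error(synth_config(lai_seasons = 1970), "subset")
})

test_that("identical configuration and seed reproduce outputs exactly", {
  cfg <- synth_config(n_rows = 10, n_cols = 10, seasons = 2000:2005,
                      lai_seasons = 2000:2003, seed = 99, n_stations = 2)
  a <- make_lai_cube(cfg, 2001); b <- make_lai_cube(cfg, 2001)
  expect_identical(a$cube, b$cube)
  expect_identical(a$truth, b$truth)
  expect_identical(make_met_daily(cfg), make_met_daily(cfg))
  met <- aggregate_seasons(make_met_daily(cfg), cfg$seasons)
  expect_identical(make_area_yield(cfg, met), make_area_yield(cfg, met))
})

test_that("the wheat draw honours the configured fraction exactly", {
  cfg <- synth_config(n_rows = 10, n_cols = 10, cropland_fraction = 1,
                      wheat_fraction = 0.5, seed = 12)
  lc <- make_lai_cube(cfg, 2002)
  expect_equal(sum(lc$truth), 50)
  # wheat is a subset of cropland for every season
  cfg2 <- synth_config(n_rows = 20, n_cols = 20, seed = 12)
  crop <- make_cropland_mask(cfg2)
  for (y in c(2000, 2008, 2019)) {
    tr <- make_lai_cube(cfg2, y, cropland = crop)$truth
    expect_true(all(crop[tr == 1] == 1))
  }
})

test_that("met generator drift, noise toggles and disabling work", {
  # noise off, no drift: equal-length non-leap windows give identical T
  cfg0 <- synth_config(seasons = 2017:2019, met_trend = 0,
                       temp_noise_sd = 0, anomaly_sd = c(T = 0, P = 0, h = 0),
                       n_stations = 2, seed = 5)
  met0 <- aggregate_seasons(make_met_daily(cfg0), cfg0$seasons)
  # 2018 and 2019 both have 238-day windows with identical doy profiles
  expect_equal(met0$T[met0$season == 2018], met0$T[met0$season == 2019],
               tolerance = 1e-9)

  # precipitation disabled
  cfgp <- synth_config(seasons = 2015:2017, precip_scale = 0, seed = 5,
                       n_stations = 2)
  md <- make_met_daily(cfgp)
  expect_true(all(md$precip_mm == 0))

  # the configured accumulated-temperature drift is recovered by OLS
  # (averaged over replicates: the per-seed slope SE is ~7% of the drift)
  slopes <- vapply(17:21, function(s) {
    cfg <- synth_config(seed = s)   # met_trend 116.91 over 40 seasons
    met <- aggregate_seasons(make_met_daily(cfg), cfg$seasons)
    unname(coef(lm(met$T ~ I(met$season / 10)))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 116.91) / 116.91, 0.10)
})

test_that("area/yield series conserve their stored components", {
  cfg <- synth_config(seed = 23, seasons = 1990:2019,
                      change_points = list(area = 2005))
  met <- aggregate_seasons(make_met_daily(cfg), cfg$seasons)
  sr <- make_area_yield(cfg, met)
  for (nm in c("area", "yield")) {
    s <- sr[[nm]]
    expect_equal(s$value, s$trend + s$climatic + s$noise, tolerance = 1e-12)
  }
  # the injected shift lives in the trend component
  tr <- sr$area$trend
  jump <- diff(tr)[sr$area$season[-1] == 2005]
  expect_gt(jump, cfg$change_magnitude * 120 * 0.5)
  expect_identical(sr$mutation_years, list(area = 2005))
})

test_that("degenerate series configurations behave analytically", {
  cfg <- synth_config(seed = 41, seasons = 1995:2019,
                      yield_weights = c(T = 0, P = 0, h = 0),
                      series_noise_sd = 0)
  met <- aggregate_seasons(make_met_daily(cfg), cfg$seasons)
  sr <- make_area_yield(cfg, met)
  expect_equal(sr$yield$value, sr$yield$trend, tolerance = 1e-12)

  # single positive T weight, flat trend, no noise: exact collinearity
  # with the standardized temperature anomaly
  cfgT <- synth_config(seed = 41, seasons = 1995:2019, trend_scale = 0,
                       yield_weights = c(T = 1, P = 0, h = 0),
                       series_noise_sd = 0)
  srT <- make_area_yield(cfgT, met)
  u <- seq_along(met$season)
  t_anom <- resid(lm(met$T ~ u))
  expect_equal(cor(srT$yield$value, t_anom), 1, tolerance = 1e-12)

  expect_error(make_area_yield(cfg, met[-3, ]), "does not cover")
})

test_that("raw yield-sunshine correlation is negative across replicates", {
  negatives <- 0
  for (s in 1:15) {
    cfg <- synth_config(seed = 600 + s)
    met <- aggregate_seasons(make_met_daily(cfg), cfg$seasons)
    sr <- make_area_yield(cfg, met)
    negatives <- negatives + (cor(sr$yield$value, met$h) < 0)
  }
  expect_gte(negatives, 14)
})

test_that("LAI cubes round-trip through the plain-text format", {
  cfg <- synth_config(n_rows = 6, n_cols = 5, n_composites = 8, seed = 2)
  lc <- make_lai_cube(cfg, 2004)
  path <- file.path(tempfile("cube"), "c.csv")
  dir.create(dirname(path))
  write_lai_cube(lc$cube, path)
  back <- read_lai_cube(path)
  expect_equal(unclass(back), unclass(lc$cube), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "dates"), attr(lc$cube, "dates"))
  expect_equal(attr(back, "transform"), attr(lc$cube, "transform"))

  write_mask(lc$truth, file.path(dirname(path), "m.csv"))
  m <- read_mask(file.path(dirname(path), "m.csv"))
  expect_equal(unname(m), unname(lc$truth), ignore_attr = TRUE)
})
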
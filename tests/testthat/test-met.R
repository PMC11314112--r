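test_that("the growing window runs day 273 of y-1 through day 145 of y", {
  w <- season_window(2019)
  expect_equal(w$start, as.Date("2018-09-30"))
  expect_equal(w$end, as.Date("2019-05-25"))
  expect_equal(w$n_days, 238)

  # leap harvest year: ordinal day 145 lands one calendar day earlier
  w20 <- season_window(2020)
  expect_equal(w20$end, as.Date("2020-05-24"))

  # leap sowing year: one extra day in the window
  w17 <- season_window(2017)   # 2016 is leap
  expect_equal(w17$n_days, 239)
})

# two constant-temperature stations over any window
constant_daily <- function(years, tmax, tmin, precip = 0, sun = 8,
                           stations = c("A", "B")) {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years) - 1)),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  do.call(rbind, lapply(seq_along(stations), function(i) {
    data.frame(date = dates, station = stations[i],
               tmax_c = tmax[i], tmin_c = tmin[i],
               precip_mm = precip, sunshine_h = sun)
  }))
}

test_that("seasonal aggregation sums daily means over the window", {
  # constant 15 degC daily mean over the 238-day window
  daily <- constant_daily(2019, tmax = c(20, 20), tmin = c(10, 10))
  agg <- aggregate_season(daily, 2019)
  expect_equal(agg$T, 15 * 238)
  expect_equal(agg$P, 0)
  expect_equal(agg$h, 8 * 238)
  expect_equal(agg$stations_used, 2)

  # provincial value is the unweighted station mean
  daily2 <- constant_daily(2019, tmax = c(17.605, 19.286),
                           tmin = c(7.605, 9.286))
  agg2 <- aggregate_season(daily2, 2019)
  t_a <- 12.605 * 238; t_b <- 14.286 * 238
  expect_equal(agg2$T, (t_a + t_b) / 2)
})

test_that("aggregation is additive over a window split", {
  cfg <- synth_config(seed = 2, seasons = 2014:2016, n_stations = 2)
  daily <- make_met_daily(cfg)
  full <- aggregate_season(daily, 2015)
  w <- season_window(2015)
  cut <- as.Date("2015-01-31")
  part1 <- daily[as.Date(daily$date) <= cut, ]
  part2 <- daily[as.Date(daily$date) > cut, ]
  sum_part <- function(d) {
    d <- d[as.Date(d$date) >= w$start & as.Date(d$date) <= w$end, ]
    by_st <- split(d, d$station)
    mean(vapply(by_st, function(s) sum((s$tmax_c + s$tmin_c) / 2),
                numeric(1)))
  }
  expect_equal(sum_part(part1) + sum_part(part2), full$T, tolerance = 1e-9)
})

test_that("shifting all dates by a year shifts the season, not the values", {
  years <- 2018:2019
  dates <- seq(as.Date("2016-07-01"), as.Date("2019-06-30"), by = "day")
  doy <- as.integer(format(dates, "%j"))
  daily <- data.frame(date = dates, station = "A",
                      tmax_c = 20 + 10 * cos(2 * pi * (doy - 205) / 365),
                      tmin_c = 10 + 10 * cos(2 * pi * (doy - 205) / 365),
                      precip_mm = 0, sunshine_h = 7)
  a18 <- aggregate_season(daily, 2018)
  a19 <- aggregate_season(daily, 2019)   # same doy profile, non-leap pair
  expect_equal(a18$T, a19$T, tolerance = 1e-9)
})

test_that("missing days are filled within tolerance, rejected beyond it", {
  daily <- constant_daily(2019, tmax = c(20, 20), tmin = c(10, 10))
  w <- season_window(2019)
  win_dates <- seq(w$start, w$end, by = "day")

  # drop 5 interior days from one station: linear interpolation restores them
  drop <- win_dates[c(40, 41, 90, 150, 200)]
  thin <- daily[!(daily$station == "A" & daily$date %in% drop), ]
  agg <- aggregate_season(thin, 2019)
  expect_equal(agg$T, 15 * 238, tolerance = 1e-9)

  # drop 10% of one station's window: hard error naming the station
  drop2 <- win_dates[seq(1, 238, by = 10)]
  thin2 <- daily[!(daily$station == "B" & daily$date %in% drop2), ]
  expect_error(aggregate_season(thin2, 2019), "station B")
})
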
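#' Growing-season window for a harvest year
#'
#' The winter-wheat growing window runs from ordinal day 273 (sowing, early
#' October) of the year before harvest through ordinal day 145 (harvest,
#' late May) of the harvest year, inclusive on both ends. Ordinal days are
#' taken in each calendar year's own calendar, so the window is 238 days
#' long when the sowing year is a common year and 239 when it is a leap
#' year, and the end date shifts by one calendar day in leap harvest years.
#'
#' @param harvest_year integer harvest (season) year.
#' @return list with `start` and `end` (`Date`) and `n_days`.
#' @examples
#' season_window(2019)  # 2018-09-30 .. 2019-05-25
#' @export
season_window <- function(harvest_year) {
  harvest_year <- as.integer(harvest_year)
  start <- as.Date(sprintf("%d-01-01", harvest_year - 1)) + 272L
  end <- as.Date(sprintf("%d-01-01", harvest_year)) + 144L
  list(start = start, end = end, n_days = as.integer(end - start) + 1L)
}

#' Aggregate daily station meteorology over one growing season
#'
#' For each station, sums daily values over the [season_window()] of the
#' harvest year: accumulated temperature `T` as the sum of daily means
#' `(tmax + tmin)/2` (no base-temperature cutoff), precipitation `P` and
#' sunshine `h` as plain sums. The provincial value is the unweighted mean
#' across stations. Missing days (up to 5% per station) are linearly
#' interpolated for temperature, zero-filled for precipitation and filled
#' with the station-month mean for sunshine; a station with a larger gap
#' aborts with an error naming it.
#'
#' @param daily data.frame with columns `date` (Date or yyyy-mm-dd string),
#'   `station`, `tmax_c`, `tmin_c`, `precip_mm`, `sunshine_h`.
#' @param harvest_year harvest year of the season to aggregate.
#' @param max_missing_frac maximum tolerated fraction of missing window
#'   days per station (default 0.05).
#' @return one-row data.frame: `season`, `T` (degC), `P` (mm), `h` (hours),
#'   `stations_used`.
#' @export
aggregate_season <- function(daily, harvest_year, max_missing_frac = 0.05) {
  need <- c("date", "station", "tmax_c", "tmin_c", "precip_mm", "sunshine_h")
  if (!all(need %in% names(daily))) {
    stop("daily table needs columns: ", paste(need, collapse = ", "))
  }
  daily$date <- as.Date(daily$date)
  aggregate_season_split(split(daily, daily$station), harvest_year,
                         max_missing_frac)
}

# workhorse on a per-station split (lets multi-season callers split once)
aggregate_season_split <- function(by_station, harvest_year,
                                   max_missing_frac = 0.05) {
  win <- season_window(harvest_year)
  dates <- seq(win$start, win$end, by = "day")
  key <- as.numeric(dates)
  stations <- sort(names(by_station))
  per_station <- vapply(stations, function(st) {
    d <- by_station[[st]]
    idx <- match(key, as.numeric(d$date))
    n_missing <- sum(is.na(idx))
    if (n_missing / length(dates) > max_missing_frac) {
      stop(sprintf(
        "station %s misses %d of %d days in the %d growing window",
        st, n_missing, length(dates), harvest_year))
    }
    tmean <- (d$tmax_c[idx] + d$tmin_c[idx]) / 2
    tmean <- zoo::na.approx(tmean, x = as.numeric(dates),
                            na.rm = FALSE, rule = 2)
    precip <- d$precip_mm[idx]
    precip[is.na(precip)] <- 0
    sun <- d$sunshine_h[idx]
    if (anyNA(sun)) {
      mon <- as.integer(format(dates, "%m"))
      mon_all <- as.integer(format(d$date, "%m"))
      for (m in unique(mon[is.na(sun)])) {
        fill <- mean(d$sunshine_h[mon_all == m], na.rm = TRUE)
        sun[is.na(sun) & mon == m] <- fill
      }
    }
    c(T = sum(tmean), P = sum(precip), h = sum(sun))
  }, numeric(3))
  data.frame(season = harvest_year,
             T = mean(per_station["T", ]),
             P = mean(per_station["P", ]),
             h = mean(per_station["h", ]),
             stations_used = length(stations))
}

#' Aggregate daily meteorology over a range of seasons
#'
#' @param daily daily meteorology table (see [aggregate_season()]).
#' @param harvest_years vector of harvest years.
#' @param max_missing_frac passed to [aggregate_season()].
#' @return data.frame with one row per season: `season`, `T`, `P`, `h`,
#'   `stations_used`.
#' @export
aggregate_seasons <- function(daily, harvest_years, max_missing_frac = 0.05) {
  daily$date <- as.Date(daily$date)
  by_station <- split(daily, daily$station)
  out <- lapply(harvest_years, function(y) {
    aggregate_season_split(by_station, y, max_missing_frac = max_missing_frac)
  })
  do.call(rbind, out)
}
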
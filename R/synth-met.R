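#' Synthetic daily station meteorology
#'
#' Generates daily records (`date`, `station`, `tmax_c`, `tmin_c`,
#' `precip_mm`, `sunshine_h`) for every station from 1 July before the
#' first season to 30 June of the last. The daily mean temperature is a
#' sinusoidal annual cycle plus a linear drift that accumulates to
#' `met_trend` degC of growing-season accumulated temperature per decade,
#' plus a per-season anomaly and day-to-day noise; `tmax`/`tmin` bracket it
#' by a fixed 10 degC diurnal range. Precipitation follows a seasonal
#' occurrence/amount model (wet-day probability peaking in summer, gamma
#' amounts) scaled by a per-season log-normal factor. Sunshine hours have
#' a seasonal cycle, an optional per-decade drift, a per-season anomaly,
#' and are reduced on wet days (rain means cloud), which couples sunshine
#' negatively to precipitation.
#'
#' Per-season anomalies of the three elements are drawn from a correlated
#' trivariate normal (monsoon covariation: warm seasons tend wetter, wet
#' seasons tend duller); the marginal standard deviations come from
#' `cfg$anomaly_sd` and the correlation structure is fixed (see the
#' methods vignette). The cycle constants are calibrated so that the
#' provincial growing-season aggregates sit in the emulated system's
#' ranges (accumulated temperature around 3311 degC, sunshine around
#' 1400 h, precipitation around 380 mm).
#'
#' @param cfg a [synth_config()].
#' @return data.frame of daily records; the per-season anomaly table is
#'   attached as attribute `anomalies` (season, a_T, a_P, a_h).
#' @export
make_met_daily <- function(cfg) {
  validate_synth_config(cfg)
  set.seed(stage_seed(cfg, "met"))

  y0 <- min(cfg$seasons); y1 <- max(cfg$seasons)
  dates <- seq(as.Date(sprintf("%d-07-01", y0 - 1)),
               as.Date(sprintf("%d-06-30", y1)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  year <- as.integer(format(dates, "%Y"))
  month <- as.integer(format(dates, "%m"))
  harvest <- year + as.integer(month >= 7)      # season a day belongs to
  labels <- sort(unique(harvest))

  # correlated per-season anomalies (T degC over window, log P factor, h hours)
  rho <- matrix(c(1, 0.5, -0.2,
                  0.5, 1, -0.45,
                  -0.2, -0.45, 1), 3, 3)
  z <- matrix(stats::rnorm(3 * length(labels)), ncol = 3) %*% chol(rho)
  anom <- sweep(z, 2, cfg$anomaly_sd, `*`)
  rownames(anom) <- labels
  a_of <- function(col) anom[match(harvest, labels), col]

  decades <- (harvest - cfg$seasons[1]) / 10
  w_days <- 238                                  # nominal window length
  t_cycle <- 17.71 + 11 * cos(2 * pi * (doy - 205) / 365)
  t_base <- t_cycle + cfg$met_trend * decades / w_days + a_of(1) / w_days

  p_wet <- 0.12 + 0.18 * (1 + cos(2 * pi * (doy - 205) / 365)) / 2
  s_cycle <- 7.2 + 1.8 * cos(2 * pi * (doy - 172) / 365)
  s_base <- s_cycle + cfg$sunshine_trend * decades / w_days + a_of(3) / w_days

  n_d <- length(dates)
  out <- vector("list", cfg$n_stations)
  t_off <- stats::runif(cfg$n_stations, -1, 1)
  s_off <- stats::runif(cfg$n_stations, -0.3, 0.3)
  for (st in seq_len(cfg$n_stations)) {
    tmean <- t_base + t_off[st] +
      stats::rnorm(n_d, sd = cfg$temp_noise_sd)
    wet <- stats::runif(n_d) < p_wet
    precip <- numeric(n_d)
    if (cfg$precip_scale > 0 && any(wet)) {
      precip[wet] <- stats::rgamma(sum(wet), shape = 0.9, scale = 11) *
        exp(a_of(2)[wet]) * cfg$precip_scale
    } else {
      wet[] <- FALSE
    }
    sun <- s_base + s_off[st] - 3 * wet +
      stats::rnorm(n_d, sd = 0.8 * (cfg$temp_noise_sd > 0))
    sun <- pmin(pmax(sun, 0), 14)
    out[[st]] <- data.frame(
      date = dates,
      station = sprintf("S%d", st),
      tmax_c = tmean + 5,
      tmin_c = tmean - 5,
      precip_mm = precip,
      sunshine_h = sun
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "anomalies") <- data.frame(season = labels,
                                       a_T = anom[, 1], a_P = anom[, 2],
                                       a_h = anom[, 3])
  res
}
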
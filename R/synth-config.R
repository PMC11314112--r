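#' Configuration for the synthetic-data generators
#'
#' Collects and validates every knob of the synthetic study system: raster
#' geometry, composite count, wheat fraction, seasons, noise levels, the
#' per-decade drift of growing-season accumulated temperature, and the
#' years of injected abrupt (mean-shift) changes. The defaults describe
#' the emulated study system — a warm-temperate winter-wheat province
#' observed over 40 harvest years (1980-2019) with LAI mapping over the
#' last 20 — and are documented in the methods vignette.
#'
#' @param n_rows,n_cols raster size in pixels.
#' @param n_composites LAI composites per growing season (>= 6).
#' @param wheat_fraction fraction of cropland pixels planted with wheat
#'   each season (0-1).
#' @param cropland_fraction fraction of all pixels that are cropland.
#' @param seasons harvest-year labels of the annual series.
#' @param lai_seasons harvest years with LAI cubes (subset of `seasons`;
#'   default the seasons from 2000 on, or all seasons when none reach
#'   2000).
#' @param noise_sd additive Gaussian LAI noise (LAI units).
#' @param seed integer random seed controlling every generator.
#' @param met_trend per-decade additive drift of growing-season accumulated
#'   temperature (degC/decade; default the emulated system's 116.91).
#' @param sunshine_trend per-decade drift of growing-season sunshine hours
#'   (h/decade, default -20).
#' @param temp_noise_sd day-to-day temperature noise (degC).
#' @param anomaly_sd length-3 vector: interannual seasonal-anomaly standard
#'   deviations for accumulated temperature (degC), log precipitation
#'   factor (dimensionless) and sunshine (h).
#' @param precip_scale multiplier on precipitation amounts; 0 disables
#'   precipitation entirely.
#' @param n_stations number of meteorological stations (default 7).
#' @param yield_weights length-3 named vector (T, P, h): loadings of the
#'   standardized seasonal met anomalies in the climatic component of the
#'   area/yield series; signs (+, +, -) with |T| > |P| > |h|.
#' @param series_noise_sd white-noise sd of the area/yield series, as a
#'   fraction of the climatic-component scale.
#' @param trend_scale multiplier on the rising part of the area/yield
#'   polynomial trends (1 = the emulated system's growth; 0 = flat trend,
#'   useful for collinearity experiments).
#' @param change_points named list mapping a series name ("area", "yield")
#'   to the year of an injected abrupt mean shift (empty by default).
#' @param change_magnitude size of an injected shift in units of the
#'   series' climatic-component scale.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_rows = 50, n_cols = 50, n_composites = 16,
                         wheat_fraction = 0.4, cropland_fraction = 0.7,
                         seasons = 1980:2019, lai_seasons = NULL,
                         noise_sd = 0.15, seed = 1,
                         met_trend = 116.91, sunshine_trend = -20,
                         temp_noise_sd = 1.5,
                         anomaly_sd = c(T = 60, P = 0.28, h = 40),
                         precip_scale = 1, n_stations = 7,
                         yield_weights = c(T = 1, P = 0.55, h = -0.3),
                         series_noise_sd = 0.25, trend_scale = 1,
                         change_points = list(), change_magnitude = 2) {
  if (is.null(lai_seasons)) {
    lai_seasons <- seasons[seasons >= 2000]
    if (!length(lai_seasons)) lai_seasons <- seasons
  }
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              n_composites = as.integer(n_composites),
              wheat_fraction = wheat_fraction,
              cropland_fraction = cropland_fraction,
              seasons = as.integer(seasons),
              lai_seasons = as.integer(lai_seasons),
              noise_sd = noise_sd, seed = as.integer(seed),
              met_trend = met_trend, sunshine_trend = sunshine_trend,
              temp_noise_sd = temp_noise_sd, anomaly_sd = anomaly_sd,
              precip_scale = precip_scale, n_stations = as.integer(n_stations),
              yield_weights = yield_weights,
              series_noise_sd = series_noise_sd,
              trend_scale = trend_scale,
              change_points = change_points,
              change_magnitude = change_magnitude)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_rows < 1 || cfg$n_cols < 1) stop("raster size must be positive")
  if (cfg$n_composites < 6) stop("n_composites must be >= 6")
  if (cfg$wheat_fraction < 0 || cfg$wheat_fraction > 1) {
    stop("wheat_fraction must lie in [0, 1]")
  }
  if (cfg$cropland_fraction < 0 || cfg$cropland_fraction > 1) {
    stop("cropland_fraction must lie in [0, 1]")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(cfg$anomaly_sd < 0) || cfg$temp_noise_sd < 0) {
    stop("noise standard deviations must be >= 0")
  }
  if (!all(cfg$lai_seasons %in% cfg$seasons)) {
    stop("lai_seasons must be a subset of seasons")
  }
  invisible(cfg)
}

# deterministic sub-seed for a generator stage; keeps seeds < 2^31
stage_seed <- function(cfg, stage, k = 0L) {
  base <- c(lai = 11, met = 23, series = 37, mask = 53)[[stage]]
  as.integer((as.numeric(cfg$seed) * 2654435 + base * 97 +
              as.numeric(k)) %% 2147483647)
}
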
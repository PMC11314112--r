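#' Synthetic annual planting-area and yield series with known components
#'
#' Composes each series as
#' `value = trend + climatic + noise`, where the trend is a smooth rising
#' quadratic (area in k ha, yield in tons), the climatic component is a
#' linear combination of the standardized growing-season met aggregates
#' with positive loading on accumulated temperature and precipitation and
#' a negative loading on sunshine (|T| > |P| > |h|), and the noise is
#' white Gaussian. An entry in `cfg$change_points` injects an abrupt mean
#' shift of `cfg$change_magnitude` climatic scales from that year onwards;
#' the shift is carried in the stored trend component so that the three
#' stored components always sum exactly to the emitted series.
#'
#' @param cfg a [synth_config()].
#' @param met data.frame (season, T, P, h) covering every `cfg$seasons`
#'   (e.g. from [aggregate_seasons()] on [make_met_daily()] output).
#' @return list of class `synth_series` with data.frames `area` and
#'   `yield` (columns season, value, trend, climatic, noise), `weights`,
#'   `scales`, and `mutation_years` (named list of injected shift years).
#' @export
make_area_yield <- function(cfg, met) {
  validate_synth_config(cfg)
  missing_seasons <- setdiff(cfg$seasons, met$season)
  if (length(missing_seasons)) {
    stop("met table does not cover season(s): ",
         paste(missing_seasons, collapse = ", "))
  }
  met <- met[match(cfg$seasons, met$season), ]
  set.seed(stage_seed(cfg, "series"))

  n <- length(cfg$seasons)
  u <- (seq_len(n) - 1) / max(1, n - 1)
  # standardized met anomaly: linear drift removed before scaling, so the
  # climatic component is trend-free by construction
  zs <- function(x) {
    r <- stats::resid(stats::lm(x ~ u))
    if (stats::sd(r) > 0) r / stats::sd(r) else r * 0
  }
  w <- cfg$yield_weights
  climatic_unit <- w[["T"]] * zs(met$T) + w[["P"]] * zs(met$P) +
    w[["h"]] * zs(met$h)

  scales <- c(area = 120, yield = 1.2e6)   # k ha / tons per climatic unit sd
  ts <- cfg$trend_scale %||% 1
  trends <- list(area = 3927 + ts * (1900 * u - 350 * u^2),
                 yield = 9.0e6 + ts * (2.9e7 * u - 4.0e6 * u^2))

  build <- function(nm) {
    trend <- trends[[nm]]
    cp <- cfg$change_points[[nm]]
    if (!is.null(cp)) {
      trend <- trend + cfg$change_magnitude * scales[[nm]] *
        (cfg$seasons >= cp)
    }
    climatic <- scales[[nm]] * climatic_unit
    noise <- stats::rnorm(n, sd = cfg$series_noise_sd * scales[[nm]])
    data.frame(season = cfg$seasons, value = trend + climatic + noise,
               trend = trend, climatic = climatic, noise = noise)
  }
  structure(list(area = build("area"), yield = build("yield"),
                 weights = w, scales = scales,
                 mutation_years = cfg$change_points),
            class = "synth_series")
}
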
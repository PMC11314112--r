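#' Cropland mask of the synthetic landscape
#'
#' A fixed (season-independent) byte raster marking dryland cropland
#' pixels, drawn once from the configuration seed so that every season of
#' a study shares the same land-use background.
#'
#' @param cfg a [synth_config()].
#' @return byte matrix (1 = cropland) with a `transform` attribute.
#' @export
make_cropland_mask <- function(cfg) {
  validate_synth_config(cfg)
  set.seed(stage_seed(cfg, "mask"))
  n_pix <- cfg$n_rows * cfg$n_cols
  n_crop <- round(cfg$cropland_fraction * n_pix)
  mask <- matrix(0L, cfg$n_rows, cfg$n_cols)
  mask[sample.int(n_pix, n_crop)] <- 1L
  attr(mask, "transform") <- default_transform(cfg)
  mask
}

default_transform <- function(cfg) {
  # GDAL-style affine: x0, dx, 0, y0, 0, -dy; 250 m grid
  c(0, 250, 0, cfg$n_rows * 250, 0, -250)
}

# smooth pulse: rises at `on`, falls at `off` (logistic shoulders)
lai_pulse <- function(t, on, off, k_on, k_off = k_on) {
  stats::plogis(k_on * (t - on)) * stats::plogis(-k_off * (t - off))
}

# closed-form noiseless curves on the 16-composite time scale
wheat_curve <- function(tt, dt = 0, amp = 4) {
  0.9 * lai_pulse(tt, 2.5 + dt, 15.2, 2.5) +
    (amp - 0.9) * lai_pulse(tt, 9 + dt, 13.8, 1.8)
}

summer_crop_curve <- function(tt, dt = 0, amp = 3) {
  amp * lai_pulse(tt, 14.5 + dt, 22, 2)
}

#' Synthetic seasonal LAI cube with known wheat truth
#'
#' Builds one growing season of per-pixel LAI curves. Wheat pixels follow
#' a double-feature phenology — autumn rise to a low over-wintering
#' plateau after sowing, spring green-up to the seasonal peak, senescence
#' to near zero before harvest — with per-pixel jitter on timing and peak
#' amplitude. Non-wheat cropland pixels are either a flat low cover or a
#' summer crop whose LAI only starts rising at the end of the window;
#' non-cropland pixels are constant low. Gaussian noise of sd
#' `cfg$noise_sd` is added and the result clamped at 0 (LAI cannot be
#' negative). Which cropland pixels carry wheat is re-drawn each season
#' (sampling without replacement, `round(wheat_fraction * n_cropland)`
#' pixels), so planting frequency varies across years.
#'
#' @param cfg a [synth_config()].
#' @param season harvest-year label of the season.
#' @param cropland optional cropland mask (defaults to
#'   [make_cropland_mask()] of `cfg`).
#' @return list with `cube` (`lai_cube`: array composite x row x col with
#'   attributes `dates` — day-within-window labels —, `transform`,
#'   `nodata`) and `truth` (byte wheat mask matrix).
#' @export
make_lai_cube <- function(cfg, season, cropland = NULL) {
  validate_synth_config(cfg)
  if (is.null(cropland)) cropland <- make_cropland_mask(cfg)
  set.seed(stage_seed(cfg, "lai", match(season, cfg$seasons) %||% season))

  n <- cfg$n_composites
  nr <- cfg$n_rows; nc <- cfg$n_cols
  n_pix <- nr * nc
  tt <- seq(1, 16, length.out = n)   # composite clock on the 16-composite scale

  crop_idx <- which(cropland == 1)
  n_wheat <- round(cfg$wheat_fraction * length(crop_idx))
  wheat_idx <- if (n_wheat > 0) sample(crop_idx, n_wheat) else integer(0)
  truth <- matrix(0L, nr, nc)
  truth[wheat_idx] <- 1L

  m <- matrix(0.15, n, n_pix)                    # non-cropland baseline
  other_idx <- setdiff(crop_idx, wheat_idx)
  if (length(other_idx)) {
    is_summer <- stats::runif(length(other_idx)) < 0.5
    for (p in other_idx[is_summer]) {
      m[, p] <- summer_crop_curve(tt, dt = stats::runif(1, -0.5, 0.5),
                                  amp = 3 + stats::runif(1, -0.5, 0.5))
    }
    for (p in other_idx[!is_summer]) {
      m[, p] <- 0.3 + stats::runif(1, -0.1, 0.1)
    }
  }
  for (p in wheat_idx) {
    m[, p] <- wheat_curve(tt, dt = stats::runif(1, -0.5, 0.5),
                          amp = 4 + stats::runif(1, -0.5, 0.5))
  }
  if (cfg$noise_sd > 0) {
    m <- m + stats::rnorm(length(m), sd = cfg$noise_sd)
    m[m < 0] <- 0
  }

  cube <- array(m, dim = c(n, nr, nc))
  attr(cube, "dates") <- round(seq(1, 238, length.out = n))
  attr(cube, "transform") <- default_transform(cfg)
  attr(cube, "nodata") <- -9999
  attr(cube, "season") <- season
  class(cube) <- "lai_cube"
  list(cube = cube, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
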
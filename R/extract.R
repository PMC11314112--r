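#' Phenology windows and thresholds for winter-wheat classification
#'
#' Defines the three climatic periods of the growing season as inclusive
#' composite-index windows — autumn rise (emergence after sowing), spring
#' peak (green-up maximum) and senescence (die-down before harvest) —
#' together with the LAI-maximum threshold and the relative end-of-season
#' LAI bound used to reject non-senescing pixels. Defaults are expressed
#' for a 16-composite season and scale proportionally for other composite
#' counts.
#'
#' @param n_composites composites per season (>= 6).
#' @param autumn,spring,senescence length-2 inclusive index windows; must
#'   be ordered and non-overlapping.
#' @param lai_max_threshold minimum seasonal LAI maximum for a wheat pixel
#'   (LAI units, default 2).
#' @param lai_sow_max maximum allowed smoothed LAI at the final composite,
#'   as a fraction of the seasonal peak (default 0.5).
#' @return object of class `phenology_windows`.
#' @export
phenology_windows <- function(n_composites = 16,
                              autumn = NULL, spring = NULL, senescence = NULL,
                              lai_max_threshold = 2, lai_sow_max = 0.5) {
  if (n_composites < 6) stop("need at least 6 composites per season")
  sc <- n_composites / 16
  if (is.null(autumn)) autumn <- c(1, max(2, round(5 * sc)))
  if (is.null(spring)) spring <- c(round(8 * sc), round(13 * sc))
  if (is.null(senescence)) senescence <- c(round(14 * sc), n_composites)
  stopifnot(length(autumn) == 2, length(spring) == 2, length(senescence) == 2)
  if (autumn[2] >= spring[1] || spring[2] >= senescence[1]) {
    stop("windows must be ordered and non-overlapping: autumn < spring < senescence")
  }
  if (lai_max_threshold < 0 || lai_sow_max < 0) stop("thresholds must be >= 0")
  structure(list(n_composites = n_composites, autumn = autumn,
                 spring = spring, senescence = senescence,
                 lai_max_threshold = lai_max_threshold,
                 lai_sow_max = lai_sow_max),
            class = "phenology_windows")
}

# moving average, window 3, partial at the edges; works column-wise on a
# n_composites x n_pixels matrix
smooth_curves <- function(m) {
  n <- nrow(m)
  sm <- m
  sm[2:(n - 1), ] <- (m[1:(n - 2), , drop = FALSE] +
                      m[2:(n - 1), , drop = FALSE] +
                      m[3:n, , drop = FALSE]) / 3
  sm[1, ] <- (m[1, ] + m[2, ]) / 2
  sm[n, ] <- (m[n - 1, ] + m[n, ]) / 2
  sm
}

#' Phenological features of one LAI curve
#'
#' Smooths the curve with a 3-composite moving average (partial windows at
#' the edges), then reports the peak (argmax, first index on ties) and the
#' inflection indices, defined as strict sign changes of the second
#' difference of the smoothed curve; an inflection between curvature
#' positions `i` and `i+1` is recorded at index `i`. Interior nodata values
#' are linearly interpolated; a curve with leading/trailing nodata or fewer
#' than 6 valid composites is skipped.
#'
#' @param curve numeric vector of per-composite LAI, `NA` for nodata.
#' @param dates optional composite day labels (metadata only).
#' @return list with `skip` (logical); when not skipped also `peak_index`,
#'   `peak_value`, `final_value` (smoothed LAI at the last composite),
#'   `inflection_indices`, `smoothed`.
#' @export
curve_features <- function(curve, dates = NULL) {
  x <- as.numeric(curve)
  n <- length(x)
  if (sum(is.finite(x)) < 6) return(list(skip = TRUE))
  if (anyNA(x)) {
    if (is.na(x[1]) || is.na(x[n])) return(list(skip = TRUE))
    x <- zoo::na.approx(x)
  }
  sm <- as.numeric(smooth_curves(matrix(x, ncol = 1)))
  d2 <- sm[3:n] - 2 * sm[2:(n - 1)] + sm[1:(n - 2)]
  flips <- which(d2[-length(d2)] * d2[-1] < 0)
  list(skip = FALSE,
       peak_index = which.max(sm),
       peak_value = max(sm),
       final_value = sm[n],
       inflection_indices = flips + 1L,
       smoothed = sm)
}

#' Classify one pixel as winter wheat or not
#'
#' A pixel is wheat iff all four clauses hold: the smoothed-curve peak
#' falls in the spring-peak window; at least one inflection lies in the
#' autumn-rise window (emergence observed); the smoothed LAI at the final
#' composite is at most `lai_sow_max` times the peak (senescence observed);
#' and the peak reaches `lai_max_threshold`.
#'
#' @param features output of [curve_features()].
#' @param windows a [phenology_windows()] object.
#' @return 1 (wheat), 0 (not wheat), or `NA` for a skipped pixel.
#' @export
classify_pixel <- function(features, windows) {
  if (isTRUE(features$skip)) return(NA_integer_)
  w <- windows
  ok <- features$peak_index >= w$spring[1] && features$peak_index <= w$spring[2] &&
    any(features$inflection_indices >= w$autumn[1] &
        features$inflection_indices <= w$autumn[2]) &&
    features$final_value <= w$lai_sow_max * features$peak_value &&
    features$peak_value >= w$lai_max_threshold
  as.integer(ok)
}

#' Classify every pixel of an LAI cube
#'
#' Vectorized application of the [classify_pixel()] rule over a
#' composite x row x col LAI cube.
#'
#' @param cube `lai_cube` (array composite x row x col, attributes `dates`,
#'   `transform`, `nodata`) as produced by [make_lai_cube()] or
#'   [read_lai_cube()].
#' @param windows a [phenology_windows()] object.
#' @return byte wheat mask (matrix row x col, 1/0/NA) carrying the cube's
#'   geotransform as attribute `transform`.
#' @export
classify_cube <- function(cube, windows) {
  a <- unclass(cube)
  nd <- attr(cube, "nodata")
  dm <- dim(a)
  if (length(dm) != 3) stop("cube must be a composite x row x col array")
  n <- dm[1]
  m <- matrix(a, nrow = n)   # composites x pixels
  if (!is.null(nd)) m[m == nd] <- NA

  bad <- colSums(!is.finite(m)) > 0
  if (any(bad)) {
    for (p in which(bad)) {
      x <- m[, p]
      if (sum(is.finite(x)) < 6 || is.na(x[1]) || is.na(x[n])) next
      m[, p] <- zoo::na.approx(x)
    }
  }
  skip <- colSums(!is.finite(m)) > 0

  sm <- smooth_curves(m)
  sm[, skip] <- 0
  peak_idx <- max.col(t(sm), ties.method = "first")
  peak_val <- sm[cbind(peak_idx, seq_len(ncol(sm)))]
  final_val <- sm[n, ]

  d2 <- sm[3:n, , drop = FALSE] - 2 * sm[2:(n - 1), , drop = FALSE] +
    sm[1:(n - 2), , drop = FALSE]
  # inflection recorded at index i+1 when curvature flips between i+1, i+2
  flip <- d2[-nrow(d2), , drop = FALSE] * d2[-1, , drop = FALSE] < 0
  infl_idx <- row(flip) + 1L
  in_autumn <- flip & infl_idx >= windows$autumn[1] & infl_idx <= windows$autumn[2]
  has_autumn_infl <- colSums(in_autumn) > 0

  wheat <- peak_idx >= windows$spring[1] & peak_idx <= windows$spring[2] &
    has_autumn_infl &
    final_val <= windows$lai_sow_max * peak_val &
    peak_val >= windows$lai_max_threshold

  mask <- matrix(as.integer(wheat), dm[2], dm[3])
  mask[matrix(skip, dm[2], dm[3])] <- NA_integer_
  attr(mask, "transform") <- attr(cube, "transform")
  mask
}

#' Restrict a wheat mask to cropland
#'
#' Sets wheat pixels outside the cropland (dryland) mask to 0. Both grids
#' must share shape and, when present, geotransform.
#'
#' @param mask byte wheat mask (matrix, 1/0/NA).
#' @param cropland byte cropland mask (matrix, 1 = cropland).
#' @return masked wheat raster, same shape and transform as `mask`.
#' @export
apply_cropland_mask <- function(mask, cropland) {
  if (!identical(dim(mask), dim(cropland))) {
    stop("grid mismatch: mask is ", paste(dim(mask), collapse = "x"),
         ", cropland is ", paste(dim(cropland), collapse = "x"))
  }
  tm <- attr(mask, "transform"); tc <- attr(cropland, "transform")
  if (!is.null(tm) && !is.null(tc) && !isTRUE(all.equal(tm, tc))) {
    stop("transform mismatch: mask [", paste(tm, collapse = ", "),
         "] vs cropland [", paste(tc, collapse = ", "), "]")
  }
  out <- mask
  out[!is.na(out) & out == 1 & (is.na(cropland) | cropland != 1)] <- 0L
  out
}

#' Planting area of a wheat mask
#'
#' @param mask byte wheat mask (matrix, 1/0/NA).
#' @param pixel_area_ha area of one pixel in hectares (> 0), e.g. 6.25 for
#'   a 250 m grid.
#' @return planting area in thousand hectares (k ha).
#' @export
planting_area <- function(mask, pixel_area_ha) {
  if (!is.numeric(pixel_area_ha) || pixel_area_ha <= 0) {
    stop("pixel_area_ha must be positive")
  }
  sum(mask == 1, na.rm = TRUE) * pixel_area_ha / 1000
}

#' Planting-frequency and frequency-change maps
#'
#' Partitions the seasons into equal consecutive intervals, counts per
#' pixel the seasons with wheat presence within each interval, and takes
#' differences of consecutive interval frequencies as change maps.
#'
#' @param masks named list of wheat masks; names are season labels (years).
#' @param intervals either an integer number of equal consecutive
#'   intervals (the season count must be divisible by it), or a list of
#'   season vectors covering every mask season exactly once.
#' @return list with `frequency` (named list of integer rasters, one per
#'   interval, labelled "first-last") and `change` (named list of
#'   later-minus-earlier difference rasters for consecutive intervals).
#' @export
frequency_map <- function(masks, intervals = 4) {
  seasons <- as.integer(names(masks))
  if (anyNA(seasons)) stop("masks must be named by season year")
  ord <- order(seasons)
  masks <- masks[ord]; seasons <- seasons[ord]
  if (is.numeric(intervals) && length(intervals) == 1) {
    k <- as.integer(intervals)
    if (length(seasons) %% k != 0) {
      stop(length(seasons), " seasons cannot be split into ", k,
           " equal intervals")
    }
    intervals <- split(seasons, rep(seq_len(k), each = length(seasons) / k))
  }
  assigned <- unlist(intervals)
  stray <- setdiff(seasons, assigned)
  if (length(stray)) {
    stop("season(s) outside all intervals: ", paste(stray, collapse = ", "))
  }
  freq <- lapply(intervals, function(yrs) {
    sub <- masks[as.character(yrs)]
    out <- Reduce(`+`, lapply(sub, function(m) {
      m[is.na(m)] <- 0L
      m
    }))
    attr(out, "transform") <- attr(sub[[1]], "transform")
    out
  })
  names(freq) <- vapply(intervals, function(y) {
    paste0(min(y), "-", max(y))
  }, character(1))
  change <- list()
  if (length(freq) > 1) {
    for (i in seq_len(length(freq) - 1)) {
      change[[paste0(names(freq)[i + 1], " vs ", names(freq)[i])]] <-
        freq[[i + 1]] - freq[[i]]
    }
  }
  list(frequency = freq, change = change)
}
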
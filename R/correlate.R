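#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the p-value from the Student-t
#' transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of
#' freedom (two-sided), as computed by [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length >= 3, finite, each with
#'   non-zero variance.
#' @return list with `r`, `p` and `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Correlation table of met drivers against area and yield
#'
#' Builds the 3 x 4 grid of Pearson correlations between the growing-season
#' meteorological factors (rows: accumulated temperature `T`, precipitation
#' `P`, sunshine hours `h`) and four targets (columns: planting area, its
#' annual difference, yield, its annual difference), with two-sided
#' p-values, significance stars (`*` p < 0.05, `**` p < 0.01) and, per
#' target, the factor ranking by |r|. Annual differences are indexed by
#' the later year and paired with that year's met levels; set
#' `diff_met = TRUE` to pair them with differenced met factors instead.
#'
#' With `detrended = TRUE` the level columns correlate the HP-filter
#' climatic components of area/yield with the HP climatic components of
#' the met factors (`lam = 100`), instead of raw levels. Level
#' correlations of jointly trending series mostly measure their shared
#' trends; the detrended grid isolates the interannual (climate-driven)
#' association and is the appropriate view for sign/weight recovery
#' experiments.
#'
#' @param met data.frame (season, T, P, h).
#' @param area,yield data.frames (season, value) aligned to `met` seasons.
#' @param diff_met pair annual differences with differenced met factors
#'   (default FALSE: met levels).
#' @param detrended correlate HP climatic components instead of raw
#'   levels (default FALSE).
#' @param lam HP smoothing parameter used when `detrended = TRUE`.
#' @return object of class `corr_table`: list with `table` (data.frame of
#'   factor, target, r, p, stars) and `ranking` (named list: factors in
#'   decreasing |r| per target).
#' @export
build_corr_table <- function(met, area, yield, diff_met = FALSE,
                             detrended = FALSE, lam = 100) {
  if (!all(met$season %in% area$season) || !all(met$season %in% yield$season)) {
    stop("area/yield seasons do not cover the met seasons")
  }
  area <- area[match(met$season, area$season), ]
  yield <- yield[match(met$season, yield$season), ]

  lev <- met[, c("T", "P", "h")]
  area_lev <- area$value
  yield_lev <- yield$value
  if (detrended) {
    lev <- as.data.frame(lapply(lev, function(x) hp_filter(x, lam)$climatic))
    area_lev <- hp_filter(area_lev, lam)$climatic
    yield_lev <- hp_filter(yield_lev, lam)$climatic
  }
  later <- -1L                               # drop first year for differences
  fac_for_diff <- if (diff_met) {
    lapply(lev, diff)
  } else {
    lapply(lev, function(x) x[later])
  }
  targets <- list(
    area = list(y = area_lev, x = lev),
    d_area = list(y = diff(area$value), x = fac_for_diff),
    yield = list(y = yield_lev, x = lev),
    d_yield = list(y = diff(yield$value), x = fac_for_diff)
  )

  rows <- list()
  ranking <- list()
  for (tg in names(targets)) {
    y <- targets[[tg]]$y
    rs <- vapply(c("T", "P", "h"), function(f) {
      pr <- pearson_with_p(targets[[tg]]$x[[f]], y)
      c(pr$r, pr$p)
    }, numeric(2))
    rows[[tg]] <- data.frame(factor = c("T", "P", "h"), target = tg,
                             r = rs[1, ], p = rs[2, ],
                             stars = significance_stars(rs[2, ]))
    ranking[[tg]] <- c("T", "P", "h")[order(-abs(rs[1, ]))]
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 ranking = ranking, n = nrow(met)),
            class = "corr_table")
}

#' @export
print.corr_table <- function(x, digits = 3, ...) {
  wide <- stats::reshape(
    transform(x$table,
              cell = paste0(formatC(r, digits = digits, format = "f"), stars)),
    idvar = "factor", timevar = "target", direction = "wide",
    drop = c("r", "p", "stars"))
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE)
  cat("ranking by |r|:",
      paste(vapply(names(x$ranking), function(t) {
        paste0(t, ": ", paste(x$ranking[[t]], collapse = " > "))
      }, character(1)), collapse = "; "), "\n")
  invisible(x)
}
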
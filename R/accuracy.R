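#' Relative error of an extracted planting area
#'
#' \eqn{\delta = |A_e - A_r| / A_r \times 100}, the percentage relative
#' error of a remotely sensed (extracted) area against the reference
#' (statistical-yearbook) area.
#'
#' @param a_e extracted area (k ha), >= 0.
#' @param a_r reference area (k ha), > 0.
#' @return relative error in percent.
#' @examples
#' relative_error(104.16, 100)  # 4.16
#' @export
relative_error <- function(a_e, a_r) {
  if (any(!is.finite(a_e)) || any(!is.finite(a_r))) {
    stop("areas must be finite")
  }
  if (any(a_r <= 0)) stop("reference area A_r must be positive")
  if (any(a_e < 0)) stop("extracted area A_e must be non-negative")
  abs(a_e - a_r) / a_r * 100
}

#' Per-year extraction accuracy against a reference series
#'
#' Pairs extracted and reference annual areas by year, computes the
#' relative error for each year and its complement `accuracy = 100 - delta`
#' (so a 4.16% error corresponds to 95.84% accuracy), and reports the
#' arithmetic mean accuracy.
#'
#' @param extracted data.frame with columns `year` and `area_kha`.
#' @param reference data.frame with columns `year` and `area_kha`; must
#'   cover exactly the same years.
#' @return object of class `accuracy_report`: list with `per_year`
#'   (data.frame: year, A_e, A_r, delta, accuracy) and `mean_accuracy`.
#' @export
accuracy_series <- function(extracted, reference) {
  for (nm in c("year", "area_kha")) {
    if (!nm %in% names(extracted) || !nm %in% names(reference)) {
      stop("extracted and reference need columns 'year' and 'area_kha'")
    }
  }
  miss_r <- setdiff(extracted$year, reference$year)
  miss_e <- setdiff(reference$year, extracted$year)
  if (length(miss_r) || length(miss_e)) {
    stop("year mismatch; missing from reference: [",
         paste(miss_r, collapse = ", "), "], missing from extracted: [",
         paste(miss_e, collapse = ", "), "]")
  }
  extracted <- extracted[order(extracted$year), ]
  reference <- reference[order(reference$year), ]
  delta <- relative_error(extracted$area_kha, reference$area_kha)
  per_year <- data.frame(
    year = extracted$year,
    A_e = extracted$area_kha,
    A_r = reference$area_kha,
    delta = delta,
    accuracy = 100 - delta
  )
  structure(list(per_year = per_year,
                 mean_accuracy = mean(per_year$accuracy)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Extraction accuracy over", nrow(x$per_year), "year(s)\n")
  print(x$per_year, row.names = FALSE)
  cat(sprintf("mean accuracy: %.2f%%\n", x$mean_accuracy))
  invisible(x)
}
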
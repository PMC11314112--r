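#' Hodrick-Prescott decomposition of an annual series
#'
#' Splits a series into a smooth trend and a high-frequency "climatic"
#' residual by minimizing
#' \eqn{\sum_t (x_t - \tau_t)^2 + \lambda \sum_t (\Delta^2 \tau_t)^2}.
#' The system is solved exactly in the form
#' \eqn{\tau = x - D'(DD' + I/\lambda)^{-1} D x}, where \eqn{D} is the
#' second-difference operator; this is algebraically identical to solving
#' \eqn{(I + \lambda D'D)\tau = x} but remains well conditioned for both
#' very small and very large \eqn{\lambda}. As \eqn{\lambda \to \infty} the
#' trend tends to the least-squares line; as \eqn{\lambda \to 0} it tends
#' to the series itself.
#'
#' @param series numeric vector, length >= 4, finite.
#' @param lam positive smoothing parameter; 100 is the usual choice for
#'   annual data (6.25 is a documented stricter alternative).
#' @param years optional year labels aligned to `series`.
#' @return object of class `hp_decomp`: list with `series`, `trend`,
#'   `climatic` (`series - trend`, exact), `annual_diff` (first differences,
#'   named by the later year when `years` is given), `lam`, `years`.
#' @examples
#' d <- hp_filter(c(10, 12, 11, 15, 14, 18, 17, 21), lam = 100)
#' all.equal(d$trend + d$climatic, d$series)
#' @export
hp_filter <- function(series, lam = 100, years = NULL) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 4) stop("hp_filter() needs at least 4 observations, got ", n)
  if (!is.numeric(lam) || length(lam) != 1 || lam <= 0) {
    stop("lam must be a single positive number")
  }
  if (any(!is.finite(x))) stop("hp_filter(): all values must be finite")
  if (is.null(years)) years <- seq_len(n)

  D <- second_diff_matrix(n)
  Dx <- D %*% x
  A <- tcrossprod(D) + diag(1 / lam, n - 2)
  trend <- x - as.numeric(crossprod(D, solve(A, Dx)))

  structure(list(
    series = x, trend = trend, climatic = x - trend,
    annual_diff = annual_difference(x, years = years),
    lam = lam, years = years
  ), class = "hp_decomp")
}

second_diff_matrix <- function(n) {
  D <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  D
}

#' Annual (first) differences of a series
#'
#' \eqn{\Delta x_t = x_t - x_{t-1}}, indexed by the later year.
#'
#' @param series numeric vector, length >= 2.
#' @param years optional year labels; differences are named by the later year.
#' @return numeric vector of length `length(series) - 1`.
#' @examples
#' annual_difference(c(100, 103, 101), years = 2000:2002)
#' @export
annual_difference <- function(series, years = NULL) {
  x <- as.numeric(series)
  if (length(x) < 2) stop("annual_difference() needs at least 2 observations")
  d <- diff(x)
  if (!is.null(years)) names(d) <- years[-1]
  d
}

#' @export
print.hp_decomp <- function(x, ...) {
  cat("HP decomposition (n =", length(x$series), ", lambda =", x$lam, ")\n")
  cat(sprintf("  sd(series) = %.4g, sd(trend) = %.4g, sd(climatic) = %.4g\n",
              stats::sd(x$series), stats::sd(x$trend), stats::sd(x$climatic)))
  invisible(x)
}
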
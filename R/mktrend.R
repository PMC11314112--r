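#' Mann-Kendall S and Z statistics
#'
#' Computes the Mann-Kendall pairwise-sign statistic
#' \eqn{S = \sum_{j<i} \mathrm{sign}(x_i - x_j)} and its standardized form
#' \eqn{Z}, using the tie-corrected variance
#' \eqn{\mathrm{Var}(S) = [n(n-1)(2n+5) - \sum_p t_p(t_p-1)(2t_p+5)]/18}
#' and the usual continuity correction (\eqn{S-1} for \eqn{S>0},
#' \eqn{S+1} for \eqn{S<0}, \eqn{Z=0} when \eqn{S=0}).
#'
#' @param values numeric vector of ordered (annual) observations, length >= 4,
#'   all finite.
#' @return list with elements `S` (integer-valued), `Z`, `var_s` and `n`.
#' @examples
#' mk_statistic(c(1, 3, 2, 4, 5, 7, 6, 8))
#' @export
mk_statistic <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4) stop("mk_statistic() needs at least 4 observations, got ", n)
  if (any(!is.finite(values))) stop("mk_statistic(): all values must be finite")

  d <- sign(outer(values, values, "-"))   # d[i, j] = sign(x_i - x_j)
  S <- sum(d[lower.tri(d)])

  ties <- table(values)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
            sum(ties * (ties - 1) * (2 * ties + 5))) / 18

  Z <- if (S > 0) {
    (S - 1) / sqrt(var_s)
  } else if (S < 0) {
    (S + 1) / sqrt(var_s)
  } else {
    0
  }
  if (!is.finite(Z)) Z <- 0  # fully tied series: var_s = 0, S = 0

  list(S = S, Z = Z, var_s = var_s, n = n)
}

#' Sequential Mann-Kendall UF/UB statistics
#'
#' Progressive/retrograde sequential statistics in the Sneyers formulation.
#' For each index \eqn{i}, the cumulative count of pairs \eqn{x_k > x_j}
#' (\eqn{j < k \le i}) is standardized with mean \eqn{i(i-1)/4} and variance
#' \eqn{i(i-1)(2i+5)/72}, giving the forward curve UF. UB is the same
#' statistic computed on the reversed series, negated and re-reversed, so
#' that an in-band crossing of UF and UB marks an abrupt change (mutation).
#' Both curves start from 0 at their respective ends. Tied pairs count
#' one half in the exceedance sum, which pins a constant series exactly
#' at the null mean (UF and UB identically zero); no further tie
#' correction is applied to the sequential variance.
#'
#' @param values numeric vector, length >= 4, finite.
#' @param alpha two-sided significance level used for the reported critical
#'   value (default 0.05, giving `z_crit` 1.96).
#' @return list with `UF`, `UB` (same length as `values`), `alpha`, `z_crit`.
#' @export
sequential_uf_ub <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4) stop("sequential_uf_ub() needs at least 4 observations, got ", n)
  if (any(!is.finite(values))) stop("sequential_uf_ub(): all values must be finite")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  list(UF = uf_curve(values), UB = -rev(uf_curve(rev(values))),
       alpha = alpha, z_crit = stats::qnorm(1 - alpha / 2))
}

# forward sequential statistic; tied pairs contribute 1/2 so that a fully
# tied (constant) series sits exactly at the null mean, i.e. UF identically 0
uf_curve <- function(x) {
  n <- length(x)
  r <- vapply(seq_len(n), function(k) {
    prev <- x[seq_len(k - 1)]
    sum(x[k] > prev) + 0.5 * sum(x[k] == prev)
  }, numeric(1))
  s <- cumsum(r)
  i <- seq_len(n)
  e <- i * (i - 1) / 4
  v <- i * (i - 1) * (2 * i + 5) / 72
  uf <- numeric(n)
  pos <- v > 0
  uf[pos] <- (s[pos] - e[pos]) / sqrt(v[pos])
  uf
}

#' Detect mutation years from UF/UB crossings
#'
#' A mutation (abrupt-change) year is reported where the sign of `UF - UB`
#' changes strictly between consecutive indices and the linearly
#' interpolated crossing value lies within `[-z_crit, +z_crit]`. When the
#' difference passes through an exact-zero run flanked by opposite signs,
#' the first year of the run is reported. Crossing years are located by
#' linear interpolation and rounded to the nearest year.
#'
#' @param UF,UB numeric vectors of equal length (sequential statistics).
#' @param z_crit positive critical value bounding admissible crossings
#'   (default 1.96).
#' @param years optional vector of year labels aligned to `UF`; defaults to
#'   `seq_along(UF)`.
#' @return numeric vector of detected mutation years (possibly empty).
#' @export
detect_mutations <- function(UF, UB, z_crit = 1.96, years = NULL) {
  if (length(UF) != length(UB)) stop("UF and UB must have the same length")
  n <- length(UF)
  if (is.null(years)) years <- seq_len(n)
  if (length(years) != n) stop("years must align with UF/UB")
  d <- UF - UB
  out <- numeric(0)
  i <- 1L
  while (i < n) {
    if (d[i] != 0 && d[i + 1] != 0 && sign(d[i]) != sign(d[i + 1])) {
      frac <- d[i] / (d[i] - d[i + 1])
      cross <- UF[i] + frac * (UF[i + 1] - UF[i])
      if (abs(cross) <= z_crit) {
        out <- c(out, round(years[i] + frac * (years[i + 1] - years[i])))
      }
      i <- i + 1L
    } else if (d[i] != 0 && d[i + 1] == 0) {
      # zero run: find next non-zero; a flip across the run is a crossing
      j <- i + 1L
      while (j <= n && d[j] == 0) j <- j + 1L
      if (j <= n && sign(d[j]) != sign(d[i])) {
        if (abs(UF[i + 1]) <= z_crit) out <- c(out, round(years[i + 1]))
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  sort(unique(out))
}

#' Full Mann-Kendall analysis of an annual series
#'
#' Convenience wrapper bundling [mk_statistic()], [sequential_uf_ub()] and
#' [detect_mutations()] into a single `series_mk` object.
#'
#' @param values numeric vector of annual observations.
#' @param years year labels aligned to `values` (default `seq_along(values)`).
#' @param alpha two-sided significance level (default 0.05).
#' @return object of class `series_mk`: a list with `values`, `years`, `S`,
#'   `Z`, `significant`, `UF`, `UB`, `alpha`, `z_crit`, `mutation_years`.
#' @examples
#' res <- mk_test(c(2, 1, 3, 4, 6, 5, 8, 9, 7, 10), years = 2001:2010)
#' res$Z
#' res$mutation_years
#' @export
mk_test <- function(values, years = seq_along(values), alpha = 0.05) {
  if (length(years) != length(values)) stop("years must align with values")
  st <- mk_statistic(values)
  sq <- sequential_uf_ub(values, alpha = alpha)
  structure(list(
    values = as.numeric(values), years = years,
    S = st$S, Z = st$Z, var_s = st$var_s,
    significant = abs(st$Z) > sq$z_crit,
    UF = sq$UF, UB = sq$UB, alpha = alpha, z_crit = sq$z_crit,
    mutation_years = detect_mutations(sq$UF, sq$UB, sq$z_crit, years)
  ), class = "series_mk")
}

#' @export
print.series_mk <- function(x, ...) {
  cat("Mann-Kendall test (n =", length(x$values), ")\n")
  cat(sprintf("  S = %d, Z = %.3f (%ssignificant at alpha = %g, |Z| %s %.2f)\n",
              as.integer(x$S), x$Z, if (x$significant) "" else "not ",
              x$alpha, if (x$significant) ">" else "<=", x$z_crit))
  if (length(x$mutation_years)) {
    cat("  UF/UB mutation year(s):", paste(x$mutation_years, collapse = ", "), "\n")
  } else {
    cat("  no in-band UF/UB crossing detected\n")
  }
  invisible(x)
}
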
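#' Distance-weighted local regression along a chromosome
#'
#' Smooths a per-marker statistic with a tricube-kernel local regression
#' on physical distance: for an evaluation position x0, markers within
#' `bandwidth_bp` receive weight `(1 - (d/h)^3)^3` and a weighted
#' constant (`degree = 0`, default) or weighted straight line
#' (`degree = 1`) is fitted. The curve is evaluated at every input
#' position, including positions whose own value is missing; missing
#' values never contribute weight. A position with no non-missing
#' neighbour inside the bandwidth falls back to the nearest non-missing
#' value.
#'
#' @param positions Numeric bp positions (one chromosome; need not be
#'   sorted).
#' @param values Statistic values (`NA` allowed).
#' @param bandwidth_bp Kernel half-width in bp (default 2 Mb).
#' @param degree 0 (local constant) or 1 (local linear).
#' @return Fitted values, one per input position.
#' @export
#' @examples
#' x <- seq(1, 50e6, length.out = 100)
#' fit_distance(x, sin(x / 5e6) + rnorm(100, 0, .1))[1:5]
fit_distance <- function(positions, values, bandwidth_bp = 2e6, degree = 0L) {
  if (bandwidth_bp <= 0) stop("bandwidth_bp must be positive")
  if (length(positions) != length(values)) {
    stop("positions and values differ in length")
  }
  if (!degree %in% c(0L, 1L)) stop("degree must be 0 or 1")
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  ord <- order(positions[ok])
  x <- positions[ok][ord]
  y <- values[ok][ord]
  h <- bandwidth_bp
  lo <- findInterval(positions - h, x) + 1L       # first index with x >= p - h
  hi <- findInterval(positions + h, x)            # last index with x <= p + h
  fitted <- vapply(seq_along(positions), function(i) {
    if (lo[i] > hi[i]) {                          # no neighbour in window
      return(y[which.min(abs(x - positions[i]))])
    }
    xi <- x[lo[i]:hi[i]]
    yi <- y[lo[i]:hi[i]]
    d <- abs(xi - positions[i]) / h
    w <- (1 - d^3)^3
    w[d >= 1] <- 0
    sw <- sum(w)
    if (sw <= 0) return(y[which.min(abs(x - positions[i]))])
    if (degree == 0L) return(sum(w * yi) / sw)
    xc <- xi - positions[i]
    s1 <- sum(w * xc); s2 <- sum(w * xc^2)
    t0 <- sum(w * yi); t1 <- sum(w * xc * yi)
    det <- sw * s2 - s1^2
    if (det <= .Machine$double.eps * sw * s2 || s2 == 0) {
      return(t0 / sw)                             # degenerate -> constant
    }
    (s2 * t0 - s1 * t1) / det
  }, numeric(1L))
  fitted
}

#' Fit a statistic track per chromosome
#'
#' Applies [fit_distance()] within each chromosome (never across
#' boundaries) and returns a scan track carrying raw and fitted values
#' plus fit metadata.
#'
#' @param records Data.frame with `chrom`, `pos` and the statistic
#'   column.
#' @param value Name of the statistic column (e.g. `"delta"`,
#'   `"ed_k"`).
#' @param bandwidth_bp,degree Passed to [fit_distance()].
#' @param absolute Smooth `|value|` instead of the signed value (used
#'   for two-sided delta scans).
#' @return The input with a `fitted` column; attributes `statistic`,
#'   `bandwidth_bp`, `degree`, `absolute`. Class `scan_track`.
#' @export
fit_track <- function(records, value, bandwidth_bp = 2e6, degree = 0L,
                      absolute = FALSE) {
  if (!value %in% names(records)) stop("no column named ", value)
  v <- records[[value]]
  if (absolute) v <- abs(v)
  fitted <- rep(NA_real_, nrow(records))
  for (chr in unique(records$chrom)) {
    sel <- records$chrom == chr
    fitted[sel] <- fit_distance(records$pos[sel], v[sel],
                                bandwidth_bp, degree)
  }
  records$fitted <- fitted
  structure(records,
    statistic = value, bandwidth_bp = bandwidth_bp,
    degree = degree, absolute = absolute,
    class = c("scan_track", "data.frame")
  )
}
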
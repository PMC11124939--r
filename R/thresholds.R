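#' Simulated null thresholds for |delta SNP-index|
#'
#' Builds confidence thresholds for the bulk SNP-index difference by
#' Monte-Carlo simulation of the no-association null: per replicate,
#' each bulk's PP05-allele count is drawn from `Binomial(2 * n_bulk,
#' 1/2)` (n_bulk unselected F2 plants contributing two alleles each),
#' reads are drawn `Binomial(depth, allele frequency)` per bulk, and
#' delta is the read-fraction difference. The threshold at confidence
#' level L and depth D is the L-quantile of `|delta|` (symmetric
#' two-sided).
#'
#' @param depths Read-depth grid (per bulk) to simulate at.
#' @param n_bulk Plants per bulk.
#' @param reps Null replicates per depth (default 10,000).
#' @param levels Confidence levels (default 0.95 and 0.99).
#' @param seed RNG seed.
#' @return A `delta_ci` data.frame: `depth`, `level`, `threshold`;
#'   attributes `n_bulk`, `reps`.
#' @export
simulate_ci <- function(depths, n_bulk, reps = 10000L,
                        levels = c(0.95, 0.99), seed = 1L) {
  depths <- sort(unique(as.integer(depths)))
  if (any(depths < 1L)) stop("depths must be >= 1")
  if (reps < 1000L) stop("reps must be at least 1000")
  if (any(levels <= 0 | levels > 1)) stop("levels must lie in (0, 1]")
  withr::with_seed(seed, {
    rows <- lapply(depths, function(d) {
      f_g <- stats::rbinom(reps, 2L * n_bulk, 0.5) / (2 * n_bulk)
      f_p <- stats::rbinom(reps, 2L * n_bulk, 0.5) / (2 * n_bulk)
      delta <- stats::rbinom(reps, d, f_p) / d -
        stats::rbinom(reps, d, f_g) / d
      thr <- stats::quantile(abs(delta), levels, names = FALSE)
      data.frame(depth = d, level = levels, threshold = thr)
    })
    structure(do.call(rbind, rows),
      n_bulk = n_bulk, reps = reps,
      class = c("delta_ci", "data.frame")
    )
  })
}

#' Look up a simulated delta threshold at arbitrary depths
#'
#' Linearly interpolates the [simulate_ci()] grid at the requested
#' depths (clamped to the grid range).
#'
#' @param ci A `delta_ci` table.
#' @param depth Depth(s) to evaluate at.
#' @param level Confidence level (must be on the grid).
#' @return Threshold value(s) for `|delta|`.
#' @export
ci_threshold <- function(ci, depth, level = 0.99) {
  sub <- ci[abs(ci$level - level) < 1e-9, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("level ", level, " not present in the simulated grid")
  }
  if (nrow(sub) == 1L) return(rep(sub$threshold, length(depth)))
  stats::approx(sub$depth, sub$threshold, xout = depth, rule = 2L)$y
}

#' Genome-wide median + 3 SD association threshold
#'
#' The association threshold for a fitted statistic track: the median of
#' the fitted values over all loci plus three sample standard
#' deviations (denominator n - 1).
#'
#' @param fitted Fitted statistic values (all chromosomes pooled).
#' @return The threshold (scalar).
#' @export
#' @examples
#' ed_threshold(c(1, 2, 3))  # 2 + 3 * 1 = 5
ed_threshold <- function(fitted) {
  fitted <- fitted[!is.na(fitted)]
  if (length(fitted) < 2L) stop("need at least 2 fitted values")
  stats::median(fitted) + 3 * stats::sd(fitted)
}
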
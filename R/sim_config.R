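#' Simulation configuration for an F2 bulked-segregant design
#'
#' Describes the simulated world: a biparental cross between two inbred
#' lines (green-sepal GP05 x purple-sepal PP05 by default), an F2
#' population segregating at biallelic markers, a single major locus with
#' additive and dominance effects on a continuous liability, a 5-class
#' ordinal phenotype cut from that liability, extreme bulks, and pooled
#' short-read sequencing of the four DNA pools (two parents, two bulks).
#'
#' Defaults reproduce the design the pipeline targets: one 100 Mb
#' chromosome carrying 10,000 markers, an F2 of 240 plants, a major locus
#' at 78 Mb with additive effect a = 3, dominance d = 0 and residual
#' standard deviation 0.5, bulks of 30 plants each, and 30x mean pool
#' depth.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp (scalar or one
#'   value per chromosome).
#' @param n_markers Total number of biallelic marker sites, allocated to
#'   chromosomes proportionally to length.
#' @param n_f2 F2 population size.
#' @param qtl_chrom,qtl_pos Location of the major locus; the realized
#'   locus is the nearest simulated marker.
#' @param qtl_effect Additive effect a: liability difference between each
#'   homozygote and the heterozygote mid-point (phenotype units).
#' @param qtl_dominance Dominance deviation d of the heterozygote.
#' @param residual_sd Standard deviation of the Gaussian residual
#'   liability.
#' @param qtl2 Optional second locus, a list with elements `chrom`, `pos`,
#'   `effect`, `dominance`; `NULL` for the default single-locus model.
#' @param n_bulk Number of plants per extreme bulk.
#' @param mean_depth Expected sequencing depth per pool per site
#'   (Poisson mean).
#' @param seq_error Per-read probability of reading the wrong allele;
#'   must lie in `[0, 0.5)`.
#' @param cm_per_mb Map density used by the Haldane map function
#'   (centimorgan per megabase).
#' @param class_breaks Liability cut points giving the five ordinal
#'   phenotype classes (green ... purple). Default: quintiles of the
#'   null (no-locus) liability distribution, `qnorm(c(.2,.4,.6,.8), 0,
#'   residual_sd)`.
#' @param indel_frac Fraction of simulated sites emitted as InDels rather
#'   than SNPs (default 0.11, the ratio typical of resequencing marker
#'   sets in this design).
#' @param seed Integer seed; every simulator operation is a pure function
#'   of its inputs and this seed.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_markers = 500, n_f2 = 100, seed = 1)
#' cfg$n_bulk
sim_config <- function(n_chromosomes = 1L,
                       chrom_length_bp = 100e6,
                       n_markers = 10000L,
                       n_f2 = 240L,
                       qtl_chrom = 1L,
                       qtl_pos = 78e6,
                       qtl_effect = 3,
                       qtl_dominance = 0,
                       residual_sd = 0.5,
                       qtl2 = NULL,
                       n_bulk = 30L,
                       mean_depth = 30,
                       seq_error = 0.001,
                       cm_per_mb = 1,
                       class_breaks = NULL,
                       indel_frac = 0.11,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = rep_len(as.numeric(chrom_length_bp), n_chromosomes),
    n_markers = as.integer(n_markers),
    n_f2 = as.integer(n_f2),
    qtl_chrom = as.integer(qtl_chrom),
    qtl_pos = as.numeric(qtl_pos),
    qtl_effect = as.numeric(qtl_effect),
    qtl_dominance = as.numeric(qtl_dominance),
    residual_sd = as.numeric(residual_sd),
    qtl2 = qtl2,
    n_bulk = as.integer(n_bulk),
    mean_depth = as.numeric(mean_depth),
    seq_error = as.numeric(seq_error),
    cm_per_mb = as.numeric(cm_per_mb),
    class_breaks = class_breaks %||%
      stats::qnorm(c(0.2, 0.4, 0.6, 0.8), 0, as.numeric(residual_sd)),
    indel_frac = as.numeric(indel_frac),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c(
    n_chromosomes = cfg$n_chromosomes, n_markers = cfg$n_markers,
    n_f2 = cfg$n_f2, n_bulk = cfg$n_bulk
  )
  bad <- counts <= 0L
  if (any(bad)) {
    stop("counts must be positive: ", paste(names(counts)[bad], collapse = ", "))
  }
  if (any(cfg$chrom_length_bp <= 0)) stop("chrom_length_bp must be positive")
  if (2L * cfg$n_bulk > cfg$n_f2) {
    stop("2 * n_bulk must not exceed n_f2")
  }
  if (cfg$seq_error < 0 || cfg$seq_error >= 0.5) {
    stop("seq_error must lie in [0, 0.5)")
  }
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive")
  if (cfg$residual_sd <= 0) stop("residual_sd must be positive")
  if (cfg$qtl_chrom < 1L || cfg$qtl_chrom > cfg$n_chromosomes ||
      cfg$qtl_pos < 1 || cfg$qtl_pos > cfg$chrom_length_bp[cfg$qtl_chrom]) {
    stop("qtl position outside the simulated genome")
  }
  if (!is.null(cfg$qtl2)) {
    q2 <- cfg$qtl2
    need <- c("chrom", "pos", "effect", "dominance")
    if (!all(need %in% names(q2))) {
      stop("qtl2 must be a list with elements chrom, pos, effect, dominance")
    }
    if (q2$chrom < 1L || q2$chrom > cfg$n_chromosomes ||
        q2$pos < 1 || q2$pos > cfg$chrom_length_bp[q2$chrom]) {
      stop("qtl2 position outside the simulated genome")
    }
  }
  brk <- cfg$class_breaks
  if (length(brk) != 4L || is.unsorted(brk, strictly = TRUE)) {
    stop("class_breaks must be 4 strictly increasing liability cut points")
  }
  pc <- class_probabilities(cfg)
  if (pc[1L] * cfg$n_f2 < 1 || pc[5L] * cfg$n_f2 < 1) {
    stop(
      "class thresholds leave an extreme phenotype class empty in ",
      "expectation (class 1: ", signif(pc[1L] * cfg$n_f2, 3),
      ", class 5: ", signif(pc[5L] * cfg$n_f2, 3), " expected plants)"
    )
  }
  cfg
}

# Expected phenotype-class probabilities under the F2 genotype mixture
# (1/4, 1/2, 1/4) at the major locus and Gaussian residual liability.
class_probabilities <- function(cfg) {
  mu <- c(
    -cfg$qtl_effect,               # code 0 (GP05 homozygote)
    cfg$qtl_dominance,             # code 1 (heterozygote)
    cfg$qtl_effect                 # code 2 (PP05 homozygote)
  )
  w <- c(0.25, 0.5, 0.25)
  brk <- c(-Inf, cfg$class_breaks, Inf)
  p <- sapply(seq_len(5L), function(k) {
    sum(w * (stats::pnorm(brk[k + 1L], mu, cfg$residual_sd) -
               stats::pnorm(brk[k], mu, cfg$residual_sd)))
  })
  p
}

#' @export
print.sim_config <- function(x, ...) {
  cat("F2 bulked-segregant simulation config\n")
  cat(sprintf(
    "  genome: %d chromosome(s), %s Mb, %d markers\n",
    x$n_chromosomes, paste(round(x$chrom_length_bp / 1e6, 1), collapse = "/"),
    x$n_markers
  ))
  cat(sprintf(
    "  population: n_f2 = %d, bulks of %d; locus chr%d:%d (a = %g, d = %g, sd = %g)\n",
    x$n_f2, x$n_bulk, x$qtl_chrom, x$qtl_pos,
    x$qtl_effect, x$qtl_dominance, x$residual_sd
  ))
  cat(sprintf(
    "  sequencing: mean depth %g, per-read error %g; seed %d\n",
    x$mean_depth, x$seq_error, x$seed
  ))
  invisible(x)
}
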
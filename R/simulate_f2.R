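#' Simulate an F2 population with an ordinal phenotype
#'
#' Draws marker positions, simulates F2 genotypes by dropping two
#' independent F1 gametes per plant through a Haldane recombination model
#' (no interference; map density `cm_per_mb`), and assigns each plant a
#' continuous liability and a 5-class ordinal phenotype.
#'
#' Genotype codes count copies of the PP05 (purple-parent) allele:
#' 0 = GP05 homozygote, 1 = heterozygote, 2 = PP05 homozygote. The
#' liability is `a * (g - 1) + d * [g == 1]` at the major locus (plus the
#' optional second locus) plus `Normal(0, residual_sd)` noise; classes
#' 1 (green) ... 5 (purple) are cut at `class_breaks`.
#'
#' @param config A [sim_config()].
#' @return An object of class `bsa_population`: a list with elements
#'   `genotypes` (n_f2 x n_markers integer matrix, rownames `F2_###`),
#'   `markers` (data.frame `chrom`, `pos`), `liability`,
#'   `phenotype_class`, `qtl` (requested and realized locus, marker
#'   index), and `config`.
#' @export
#' @examples
#' pop <- simulate_f2(sim_config(n_markers = 200, n_f2 = 60, seed = 1))
#' table(pop$phenotype_class)
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    markers <- draw_marker_map(config)
    geno <- matrix(0L, config$n_f2, nrow(markers))
    for (chr in seq_len(config$n_chromosomes)) {
      idx <- which(markers$chrom == chr)
      if (length(idx) == 0L) next
      r <- haldane_recomb(diff(markers$pos[idx]), config$cm_per_mb)
      geno[, idx] <- sim_gametes(config$n_f2, r) + sim_gametes(config$n_f2, r)
    }
    qtl_idx <- nearest_marker(markers, config$qtl_chrom, config$qtl_pos)
    g <- geno[, qtl_idx]
    liab <- config$qtl_effect * (g - 1) + config$qtl_dominance * (g == 1)
    qtl2 <- NULL
    if (!is.null(config$qtl2)) {
      q2_idx <- nearest_marker(markers, config$qtl2$chrom, config$qtl2$pos)
      g2 <- geno[, q2_idx]
      liab <- liab + config$qtl2$effect * (g2 - 1) +
        config$qtl2$dominance * (g2 == 1)
      qtl2 <- list(
        chrom = config$qtl2$chrom, pos = markers$pos[q2_idx],
        marker = q2_idx
      )
    }
    liab <- liab + stats::rnorm(config$n_f2, 0, config$residual_sd)
    cls <- findInterval(liab, config$class_breaks) + 1L
    rownames(geno) <- sprintf("F2_%04d", seq_len(config$n_f2))
    structure(
      list(
        genotypes = geno,
        markers = markers,
        liability = liab,
        phenotype_class = cls,
        qtl = list(
          chrom = config$qtl_chrom,
          pos_requested = config$qtl_pos,
          pos = markers$pos[qtl_idx],
          marker = qtl_idx
        ),
        qtl2 = qtl2,
        config = config
      ),
      class = "bsa_population"
    )
  })
}

#' @export
print.bsa_population <- function(x, ...) {
  cat(sprintf(
    "F2 population: %d plants x %d markers on %d chromosome(s)\n",
    nrow(x$genotypes), ncol(x$genotypes), x$config$n_chromosomes
  ))
  cat(sprintf(
    "  major locus at chr%d:%d (marker %d)\n",
    x$qtl$chrom, x$qtl$pos, x$qtl$marker
  ))
  cat("  phenotype classes:",
      paste(sprintf("%d:%d", 1:5, tabulate(x$phenotype_class, 5L)),
            collapse = " "), "\n")
  invisible(x)
}

# uniform random marker positions, allocated proportionally to length
draw_marker_map <- function(config) {
  len <- config$chrom_length_bp
  alloc <- diff(round(config$n_markers * cumsum(c(0, len)) / sum(len)))
  chrom <- rep.int(seq_len(config$n_chromosomes), alloc)
  pos <- unlist(lapply(seq_len(config$n_chromosomes), function(chr) {
    sort(sample.int(len[chr], alloc[chr]))
  }), use.names = FALSE)
  data.frame(chrom = chrom, pos = as.numeric(pos))
}

# Haldane map function: bp gap -> recombination fraction
haldane_recomb <- function(gap_bp, cm_per_mb) {
  d_morgan <- gap_bp / 1e6 * cm_per_mb / 100
  0.5 * (1 - exp(-2 * d_morgan))
}

# n gametes along one chromosome; r = recombination fractions between
# adjacent markers. Returns n x (length(r) + 1) 0/1 allele matrix.
sim_gametes <- function(n, r) {
  m <- length(r) + 1L
  first <- stats::rbinom(n, 1L, 0.5)
  if (m == 1L) return(matrix(first, ncol = 1L))
  switches <- matrix(
    stats::rbinom(n * (m - 1L), 1L, rep(r, each = n)),
    nrow = n
  )
  state <- cbind(first, switches)
  t(apply(state, 1L, cumsum)) %% 2L
}

nearest_marker <- function(markers, chrom, pos) {
  idx <- which(markers$chrom == chrom)
  if (length(idx) == 0L) stop("no markers on chromosome ", chrom)
  idx[which.min(abs(markers$pos[idx] - pos))]
}

#' Select the two extreme-phenotype bulks
#'
#' Picks `n_bulk` plants of ordinal class 1 (green) for the low bulk and
#' `n_bulk` of class 5 (purple) for the high bulk, the most extreme
#' liabilities first; ties broken by individual id. The selection is
#' deterministic given the population.
#'
#' @param pop A [simulate_f2()] population.
#' @param n_bulk Plants per bulk (default from the population's config).
#' @return A list with integer id vectors `bulk_low` and `bulk_high`
#'   (row indices into `pop$genotypes`, named by plant id).
#' @export
build_bulks <- function(pop, n_bulk = pop$config$n_bulk) {
  stopifnot(inherits(pop, "bsa_population"))
  n_bulk <- as.integer(n_bulk)
  avail <- tabulate(pop$phenotype_class, 5L)
  for (cls in c(1L, 5L)) {
    if (avail[cls] < n_bulk) {
      stop(sprintf(
        "insufficient extreme plants in class %d (%s): %d available, %d needed",
        cls, if (cls == 1L) "green" else "purple", avail[cls], n_bulk
      ))
    }
  }
  ids <- seq_len(nrow(pop$genotypes))
  low_pool <- ids[pop$phenotype_class == 1L]
  high_pool <- ids[pop$phenotype_class == 5L]
  bulk_low <- low_pool[order(pop$liability[low_pool], low_pool)][seq_len(n_bulk)]
  bulk_high <- high_pool[order(-pop$liability[high_pool], high_pool)][seq_len(n_bulk)]
  names(bulk_low) <- rownames(pop$genotypes)[bulk_low]
  names(bulk_high) <- rownames(pop$genotypes)[bulk_high]
  list(bulk_low = sort(bulk_low), bulk_high = sort(bulk_high))
}
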
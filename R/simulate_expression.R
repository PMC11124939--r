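#' Simulate a gene annotation along the simulated genome
#'
#' Places `n_genes` non-nested gene models uniformly along the genome with
#' log-normal lengths and attaches annotation strings drawn from a small
#' vocabulary of pigment-pathway and housekeeping descriptions, so that
#' keyword-based candidate reporting can be exercised.
#'
#' @param config A [sim_config()] describing the genome.
#' @param n_genes Number of genes.
#' @param seed Seed (default `config$seed + 2`).
#' @return A GeneModel data.frame: `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive), `annotation`.
#' @export
simulate_genes <- function(config, n_genes = 2000L, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    len <- config$chrom_length_bp
    alloc <- diff(round(n_genes * cumsum(c(0, len)) / sum(len)))
    chrom <- rep.int(seq_len(config$n_chromosomes), alloc)
    start <- unlist(lapply(seq_len(config$n_chromosomes), function(chr) {
      sort(sample.int(len[chr], alloc[chr]))
    }), use.names = FALSE)
    glen <- pmax(200, round(stats::rlnorm(n_genes, log(2000), 0.6)))
    end <- pmin(start + glen - 1, len[chrom])
    vocab <- c(
      "transcription factor bHLH", "MYB family transcription factor",
      "WD repeat-containing protein", "chalcone synthase",
      "chalcone-flavonone isomerase", "vacuolar-sorting receptor",
      "RNA processing and modification protein",
      "anthocyanidin synthase"
    )
    background <- c(
      "hypothetical protein", "cytochrome P450", "protein kinase",
      "ABC transporter", "ribosomal protein", "heat shock protein",
      "pentatricopeptide repeat protein"
    )
    annot <- sample(background, n_genes, replace = TRUE)
    n_special <- max(1L, round(0.02 * n_genes))
    annot[sample.int(n_genes, n_special)] <-
      sample(vocab, n_special, replace = TRUE)
    data.frame(
      gene = sprintf("GENE_%05d", seq_len(n_genes)),
      chrom = chrom, start = as.numeric(start), end = as.numeric(end),
      annotation = annot
    )
  })
}

#' Simulate a two-group RNA-seq count matrix with planted DE genes
#'
#' Generates negative-binomial fragment counts for a 3 vs 3 replicate
#' design (green line `gc` vs purple line `pc`). `n_de` genes are
#' differentially expressed with group-mean ratio `2^log2fc` (sign
#' alternating up/down); a configurable fraction of them is placed inside
#' the supplied candidate region to emulate a causal locus whose pathway
#' responds in cis and trans.
#'
#' @param config A [sim_config()].
#' @param region A [region()] the DE genes should concentrate in (or
#'   `NULL` for no placement constraint).
#' @param n_de Number of DE genes.
#' @param log2fc Absolute log2 fold change of the planted DE genes.
#' @param genes Optional GeneModel table; simulated via
#'   [simulate_genes()] when `NULL`.
#' @param n_genes Number of genes when `genes` is `NULL`.
#' @param dispersion Negative-binomial dispersion (biological replicates
#'   of inbred lines; default 0.05).
#' @param mean_log,sd_log Log-normal parameters of baseline means.
#' @param in_region_frac Fraction of DE genes placed inside `region`.
#' @param n_rep Replicates per group.
#' @param seed Seed (default `config$seed + 3`).
#' @return A list: `counts` (genes x samples integer matrix), `lengths`
#'   (bp), `groups` (sample group labels), `genes` (annotation table),
#'   `truth` (data.frame `gene`, `is_de`, `true_log2fc`, `in_region`).
#' @export
simulate_expression <- function(config, region = NULL, n_de = 100L,
                                log2fc = 2, genes = NULL, n_genes = 2000L,
                                dispersion = 0.05, mean_log = log(100),
                                sd_log = 1, in_region_frac = 0.5,
                                n_rep = 3L, seed = config$seed + 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (dispersion <= 0) stop("dispersion must be positive")
  if (log2fc < 0) stop("log2fc must be non-negative")
  if (is.null(genes)) genes <- simulate_genes(config, n_genes, seed = seed)
  n_genes <- nrow(genes)
  if (n_de > n_genes) stop("n_de exceeds the number of genes")
  withr::with_seed(seed, {
    in_region <- rep(FALSE, n_genes)
    if (!is.null(region)) {
      in_region <- genes$chrom == region$chrom &
        genes$start <= region$end & genes$end >= region$start
    }
    de_idx <- integer(0)
    if (n_de > 0L) {
      n_in <- min(round(n_de * in_region_frac), sum(in_region))
      de_idx <- c(
        sample(which(in_region), n_in),
        sample(which(!in_region), n_de - n_in)
      )
    }
    true_lfc <- numeric(n_genes)
    if (length(de_idx) > 0L) {
      true_lfc[de_idx] <- log2fc * rep_len(c(1, -1), length(de_idx))
    }
    mu_a <- stats::rlnorm(n_genes, mean_log, sd_log)
    mu_b <- mu_a * 2^true_lfc
    samples <- c(
      sprintf("gc_%d", seq_len(n_rep)), sprintf("pc_%d", seq_len(n_rep))
    )
    counts <- cbind(
      matrix(stats::rnbinom(n_genes * n_rep, mu = mu_a, size = 1 / dispersion),
             n_genes),
      matrix(stats::rnbinom(n_genes * n_rep, mu = mu_b, size = 1 / dispersion),
             n_genes)
    )
    dimnames(counts) <- list(genes$gene, samples)
    list(
      counts = counts,
      lengths = genes$end - genes$start + 1,
      groups = rep(c("gc", "pc"), each = n_rep),
      genes = genes,
      truth = data.frame(
        gene = genes$gene,
        is_de = true_lfc != 0,
        true_log2fc = true_lfc,
        in_region = in_region
      )
    )
  })
}

#' Extract a marker genotype panel from a simulated population
#'
#' Emulates the genotype tables produced by SSR/CAPS marker screening:
#' for each requested position the nearest simulated marker on that
#' chromosome is scored in every F2 plant, with optional random missing
#' calls.
#'
#' @param pop A [simulate_f2()] population.
#' @param positions Target bp positions of the designed markers.
#' @param chrom Chromosome of the markers (scalar or vector).
#' @param marker_type Marker type labels recycled over markers.
#' @param missing_rate Per-call probability of a missing genotype.
#' @param seed Seed (default `pop$config$seed + 4`).
#' @return A `marker_genotypes` object: list with `info` (data.frame
#'   `marker`, `chrom`, `pos`, `type`) and `geno` (markers x individuals
#'   matrix of codes 0/1/2 or `NA`).
#' @export
sample_markers <- function(pop, positions, chrom = pop$qtl$chrom,
                           marker_type = "SSR", missing_rate = 0.02,
                           seed = pop$config$seed + 4L) {
  stopifnot(inherits(pop, "bsa_population"))
  chrom <- rep_len(chrom, length(positions))
  idx <- mapply(function(ch, p) nearest_marker(pop$markers, ch, p),
                chrom, positions)
  geno <- t(pop$genotypes[, idx, drop = FALSE])
  withr::with_seed(seed, {
    if (missing_rate > 0) {
      geno[matrix(stats::runif(length(geno)) < missing_rate,
                  nrow(geno))] <- NA_integer_
    }
  })
  info <- data.frame(
    marker = sprintf("MK_%03d", seq_along(idx)),
    chrom = pop$markers$chrom[idx],
    pos = pop$markers$pos[idx],
    type = rep_len(marker_type, length(idx))
  )
  rownames(geno) <- info$marker
  structure(list(info = info, geno = geno), class = "marker_genotypes")
}

#' @export
print.marker_genotypes <- function(x, ...) {
  cat(sprintf(
    "marker genotype panel: %d markers x %d individuals (%s)\n",
    nrow(x$info), ncol(x$geno),
    paste(unique(x$info$type), collapse = "/")
  ))
  invisible(x)
}
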
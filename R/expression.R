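#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM[g, s] = counts[g, s] * 1e9 / (length[g] * total[s])`, where
#' `total[s]` is the library size (column sum) of sample s.
#'
#' @param counts Genes x samples non-negative integer matrix.
#' @param lengths Gene lengths in bp (one per row).
#' @return FPKM matrix with the same dimnames.
#' @export
fpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) {
    stop("need one gene length per row of the count matrix")
  }
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  counts * 1e9 / outer(as.numeric(lengths), totals)
}

#' Drop genes below the expression floor in every sample
#'
#' Keeps genes with `FPKM >= min_fpkm` in at least one sample (the
#' boundary value is kept); all-low genes are excluded from downstream
#' analysis.
#'
#' @param fpkm_mat An [fpkm()] matrix.
#' @param min_fpkm Expression floor (default 1).
#' @return Character vector of retained gene ids.
#' @export
filter_low_expression <- function(fpkm_mat, min_fpkm = 1) {
  keep <- apply(fpkm_mat >= min_fpkm, 1L, any)
  rownames(fpkm_mat)[keep]
}

# DESeq-style median-of-ratios size factors; falls back to library-size
# ratios when too few genes are expressed in every sample.
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (sum(use) >= 10L) {
    sf <- apply(counts[use, , drop = FALSE], 2L, function(col) {
      exp(stats::median(log(col) - log_geo[use]))
    })
  } else {
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
  }
  sf
}

#' Call differentially expressed genes between two groups
#'
#' A lightweight negative-binomial Wald test on library-size-normalized
#' counts: median-of-ratios normalization, group means with pseudocount
#' 0.5 for the fold change, per-gene method-of-moments dispersion
#' (pooled over the two groups, floored at 1e-8), a Wald z on the log2
#' fold change via the delta method, Benjamini-Hochberg correction, and
#' direction calls at the thresholds `FDR < fdr_max` and
#' `|log2FC| > lfc_min`.
#'
#' @param counts Genes x samples count matrix.
#' @param groups Group label per sample.
#' @param group_a,group_b The two labels to compare (fold change is
#'   `group_b` relative to `group_a`).
#' @param fdr_max,lfc_min Significance thresholds (defaults 0.01 and 1).
#' @return A DegResult data.frame: `gene`, `base_mean_a`, `base_mean_b`,
#'   `log2fc`, `stat`, `pvalue`, `fdr`, `direction` (`up`/`down`/`ns`).
#' @export
call_degs <- function(counts, groups, group_a = unique(groups)[1L],
                      group_b = unique(groups)[2L],
                      fdr_max = 0.01, lfc_min = 1) {
  counts <- as.matrix(counts)
  a_cols <- which(groups == group_a)
  b_cols <- which(groups == group_b)
  if (length(a_cols) < 2L || length(b_cols) < 2L) {
    stop("need at least 2 replicates per group")
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  na <- length(a_cols); nb <- length(b_cols)
  mu_a <- rowMeans(norm[, a_cols, drop = FALSE])
  mu_b <- rowMeans(norm[, b_cols, drop = FALSE])
  v_a <- apply(norm[, a_cols, drop = FALSE], 1L, stats::var)
  v_b <- apply(norm[, b_cols, drop = FALSE], 1L, stats::var)
  # method-of-moments NB dispersion, pooled over groups
  disp_a <- (v_a - mu_a) / pmax(mu_a, 1e-8)^2
  disp_b <- (v_b - mu_b) / pmax(mu_b, 1e-8)^2
  disp <- pmax((disp_a + disp_b) / 2, 1e-8)
  lfc <- log2((mu_b + 0.5) / (mu_a + 0.5))
  # delta-method variance of log2 of a group mean under NB sampling
  var_log2_mean <- function(mu, n) {
    (mu + disp * mu^2) / n / (mu + 0.5)^2 / log(2)^2
  }
  se <- sqrt(var_log2_mean(mu_a, na) + var_log2_mean(mu_b, nb))
  stat <- ifelse(se > 0, lfc / se, 0)
  pvalue <- 2 * stats::pnorm(-abs(stat))
  fdr <- stats::p.adjust(pvalue, method = "BH")
  direction <- rep("ns", nrow(counts))
  direction[fdr < fdr_max & lfc > lfc_min] <- "up"
  direction[fdr < fdr_max & lfc < -lfc_min] <- "down"
  data.frame(
    gene = rownames(counts) %||% seq_len(nrow(counts)),
    base_mean_a = mu_a, base_mean_b = mu_b,
    log2fc = lfc, stat = stat, pvalue = pvalue, fdr = fdr,
    direction = direction,
    row.names = NULL
  )
}

#' Pairwise replicate correlation on log2(FPKM + 1)
#'
#' Pearson correlation of every sample pair, the standard replicate
#' consistency check before differential analysis. Constant samples
#' yield `NA` and are flagged.
#'
#' @param counts Genes x samples count matrix.
#' @param lengths Gene lengths in bp.
#' @return Data.frame `sample_a`, `sample_b`, `r`, `degenerate` (one row
#'   per unordered pair).
#' @export
replicate_correlation <- function(counts, lengths) {
  lf <- log2(fpkm(counts, lengths) + 1)
  if (ncol(lf) < 2L) stop("need at least 2 samples")
  const <- apply(lf, 2L, function(x) stats::sd(x) == 0)
  cm <- suppressWarnings(stats::cor(lf))
  pairs <- utils::combn(ncol(lf), 2L)
  data.frame(
    sample_a = colnames(lf)[pairs[1L, ]],
    sample_b = colnames(lf)[pairs[2L, ]],
    r = cm[cbind(pairs[1L, ], pairs[2L, ])],
    degenerate = const[pairs[1L, ]] | const[pairs[2L, ]],
    row.names = NULL
  )
}

#' Venn partition of two gene sets
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return A list with counts `only_a`, `only_b`, `both`.
#' @export
overlap_counts <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  both <- length(intersect(set_a, set_b))
  list(
    only_a = length(set_a) - both,
    only_b = length(set_b) - both,
    both = both
  )
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric test per term (the probability of drawing
#' at least the observed number of term genes when sampling
#' `length(selected)` genes from the universe without replacement),
#' with Benjamini-Hochberg Q values across terms. Default significance
#' flags follow the conventional thresholds p <= 1e-4 (GO-style) and
#' Q <= 0.05 (pathway-style); both are configurable.
#'
#' @param selected Genes of interest (must all be in `universe`).
#' @param terms Named list mapping term id -> character vector of member
#'   genes.
#' @param universe Background gene set (e.g. all genes surviving the
#'   expression filter).
#' @param p_max,q_max Significance thresholds for the flags.
#' @return Data.frame `term`, `n_term`, `n_selected`, `n_overlap`,
#'   `expected`, `pvalue`, `qvalue`, `significant_p`, `significant_q`.
#' @export
term_enrichment <- function(selected, terms, universe,
                            p_max = 1e-4, q_max = 0.05) {
  selected <- unique(selected)
  universe <- unique(universe)
  outside <- setdiff(selected, universe)
  if (length(outside) > 0L) {
    stop("selected gene(s) absent from the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  }
  if (length(terms) == 0L || any(lengths(terms) == 0L)) {
    stop("terms must be a non-empty list of non-empty gene sets")
  }
  n_u <- length(universe)
  n_s <- length(selected)
  rows <- lapply(names(terms), function(tm) {
    members <- intersect(unique(terms[[tm]]), universe)
    k <- length(intersect(members, selected))
    m <- length(members)
    p <- stats::phyper(k - 1L, m, n_u - m, n_s, lower.tail = FALSE)
    data.frame(
      term = tm, n_term = m, n_selected = n_s, n_overlap = k,
      expected = n_s * m / n_u, pvalue = p
    )
  })
  out <- do.call(rbind, rows)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out$significant_p <- out$pvalue <= p_max
  out$significant_q <- out$qvalue <= q_max
  out
}
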
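#' Score marker-phenotype co-segregation in the bulked plants
#'
#' For each marker, compares the genotype of every bulked plant with the
#' genotype expected from its bulk membership: under the `additive`
#' model green extremes must be GP05 homozygotes (code 0) and purple
#' extremes PP05 homozygotes (code 2); under the `dominant` model purple
#' extremes may be code 1 or 2. Plants violating the expectation are
#' recombinants; a marker co-segregates iff it shows zero recombinants
#' among the scored (non-missing) plants.
#'
#' @param markers A `marker_genotypes` object ([sample_markers()] or
#'   [read_marker_genotypes()]).
#' @param bulk_low,bulk_high Ids (indices or names) of the green and
#'   purple bulk plants; must match columns of the genotype matrix.
#' @param model `"additive"` or `"dominant"`.
#' @param min_scored_frac Markers with fewer scored plants than this
#'   fraction of the bulks are flagged `low_confidence`.
#' @return A CosegregationResult data.frame: `marker`, `chrom`, `pos`,
#'   `type`, `n_scored`, `n_recombinants`, `cosegregating`,
#'   `low_confidence`.
#' @export
score_cosegregation <- function(markers, bulk_low, bulk_high,
                                model = c("additive", "dominant"),
                                min_scored_frac = 0.8) {
  model <- match.arg(model)
  stopifnot(inherits(markers, "marker_genotypes"))
  geno <- markers$geno
  as_cols <- function(ids) {
    if (is.character(ids)) {
      miss <- setdiff(ids, colnames(geno))
      if (length(miss) > 0L) {
        stop("bulk plants absent from the genotype matrix: ",
             paste(utils::head(miss, 5L), collapse = ", "))
      }
      match(ids, colnames(geno))
    } else {
      as.integer(ids)
    }
  }
  low <- as_cols(if (!is.null(names(bulk_low))) names(bulk_low) else bulk_low)
  high <- as_cols(if (!is.null(names(bulk_high))) names(bulk_high) else bulk_high)
  n_total <- length(low) + length(high)
  g_low <- geno[, low, drop = FALSE]
  g_high <- geno[, high, drop = FALSE]
  if (any(rowSums(!is.na(g_low)) + rowSums(!is.na(g_high)) == 0L)) {
    stop("marker(s) with all-missing genotypes: ",
         paste(markers$info$marker[
           rowSums(!is.na(g_low)) + rowSums(!is.na(g_high)) == 0L
         ], collapse = ", "))
  }
  viol_low <- g_low != 0L                     # green extremes: code 0
  viol_high <- if (model == "additive") {
    g_high != 2L                              # purple extremes: code 2
  } else {
    g_high == 0L                              # purple extremes: code 1 or 2
  }
  n_scored <- as.integer(rowSums(!is.na(g_low)) + rowSums(!is.na(g_high)))
  n_rec <- as.integer(
    rowSums(viol_low, na.rm = TRUE) + rowSums(viol_high, na.rm = TRUE)
  )
  data.frame(
    marker = markers$info$marker,
    chrom = markers$info$chrom,
    pos = markers$info$pos,
    type = markers$info$type,
    n_scored = n_scored,
    n_recombinants = n_rec,
    cosegregating = n_rec == 0L,
    low_confidence = n_scored < min_scored_frac * n_total
  )
}

#' Refine a candidate region by co-segregating markers
#'
#' The refined interval is bounded by the outermost co-segregating
#' markers (inclusive); markers showing any recombinant are excluded.
#' At least one co-segregating marker must lie inside the input region.
#'
#' @param results A [score_cosegregation()] table.
#' @param region The Region being refined (single row).
#' @return A one-row Region tagged `finemap`.
#' @export
#' @examples
#' res <- data.frame(
#'   marker = c("a", "b", "c"), chrom = 10,
#'   pos = c(77683697, 79000000, 80307823), type = "SSR",
#'   n_scored = 60, n_recombinants = 0, cosegregating = TRUE,
#'   low_confidence = FALSE
#' )
#' refine_interval(res, region(10, 62600000, 82400000))$length_mb  # 2.62
refine_interval <- function(results, region) {
  stopifnot(nrow(region) == 1L)
  cos <- results[results$cosegregating & results$chrom == region$chrom, ,
                 drop = FALSE]
  inside <- cos$pos >= region$start & cos$pos <= region$end
  if (nrow(cos) == 0L || !any(inside)) {
    stop(
      "no co-segregating marker inside the candidate region; ",
      "design a denser marker panel before refining"
    )
  }
  region(
    region$chrom, min(cos$pos), max(cos$pos),
    method = "finemap", n_sites = nrow(cos)
  )
}

#' Read / write marker genotype tables
#'
#' TSV layout: columns `marker`, `chrom`, `pos`, `type`, then one column
#' per F2 individual holding codes 0/1/2 or `NA`.
#'
#' @param path File path.
#' @return For the reader, a `marker_genotypes` object.
#' @export
read_marker_genotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("marker", "chrom", "pos", "type")
  miss <- setdiff(meta, names(tab))
  if (length(miss) > 0L) {
    stop("marker table is missing columns: ", paste(miss, collapse = ", "))
  }
  geno <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  storage.mode(geno) <- "integer"
  rownames(geno) <- tab$marker
  structure(
    list(info = tab[, meta], geno = geno),
    class = "marker_genotypes"
  )
}

#' @rdname read_marker_genotypes
#' @param markers A `marker_genotypes` object.
#' @export
write_marker_genotypes <- function(markers, path) {
  out <- cbind(markers$info, as.data.frame(markers$geno))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
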
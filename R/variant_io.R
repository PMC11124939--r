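#' Read a four-pool variant table
#'
#' Reads variant sites with per-pool allele depths from a VCF 4.2 file
#' (AD genotype field; parsed with VariantAnnotation) or from the
#' package's TSV mirror. The four pool samples are, in order: GP05
#' parent, PP05 parent, green bulk, purple bulk; VCF sample names are
#' configurable via `samples`.
#'
#' Multiallelic records are dropped by default; with
#' `multiallelic = "split"` each alternate allele becomes its own
#' biallelic record (reference depth shared).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"tsv"`.
#' @param samples Named character vector mapping the pool roles
#'   `gp05`, `pp05`, `green`, `purple` to VCF sample names.
#' @param multiallelic `"drop"` or `"split"`.
#' @return A VariantSite data.frame (see [simulate_pool_reads()]).
#' @export
read_variants <- function(path,
                          format = c("auto", "vcf", "tsv"),
                          samples = c(
                            gp05 = "GP05", pp05 = "PP05",
                            green = "BULK_GREEN", purple = "BULK_PURPLE"
                          ),
                          multiallelic = c("drop", "split")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    sites <- utils::read.delim(path, stringsAsFactors = FALSE)
    .check_variants(sites)
    if (any(sites$pos < 1)) {
      stop("malformed coordinates: pos < 1 at line(s) ",
           paste(utils::head(which(sites$pos < 1) + 1L, 5L), collapse = ", "))
    }
    return(sites)
  }
  read_variants_vcf(path, samples, multiallelic)
}

read_variants_vcf <- function(path, samples, multiallelic) {
  vcf <- VariantAnnotation::readVcf(path)
  have <- colnames(vcf)
  miss <- setdiff(unname(samples), have)
  if (length(miss) > 0L) {
    stop("VCF is missing pool sample(s): ", paste(miss, collapse = ", "),
         " (present: ", paste(have, collapse = ", "), ")")
  }
  if (!"AD" %in% names(VariantAnnotation::geno(vcf))) {
    stop("VCF has no AD (allelic depth) FORMAT field")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt_list <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(alt_list)
  ad <- VariantAnnotation::geno(vcf)$AD
  # AD comes back as a matrix of integer vectors (ragged) or a 3-d array
  get_ad <- function(i, sample) {
    if (is.array(ad) && length(dim(ad)) == 3L) {
      ad[i, sample, ]
    } else {
      ad[[i, sample]]
    }
  }
  keep <- which(n_alt >= 1L)
  if (multiallelic == "drop") keep <- which(n_alt == 1L)
  rows <- list()
  for (i in keep) {
    alts <- as.character(alt_list[[i]])
    alt_idx <- if (multiallelic == "split") seq_along(alts) else 1L
    for (j in alt_idx) {
      depth <- lapply(names(samples), function(role) {
        v <- get_ad(i, samples[[role]])
        if (length(v) < j + 1L || anyNA(v[c(1L, j + 1L)])) {
          stop("missing AD values for sample ", samples[[role]],
               " at record ", i)
        }
        c(v[1L], v[j + 1L])
      })
      names(depth) <- names(samples)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(rr)[i]),
        pos = GenomicRanges::start(rr)[i],
        ref = ref[i],
        alt = alts[j],
        site_type = if (nchar(ref[i]) != nchar(alts[j])) "InDel" else "SNP",
        gp05_ref = depth$gp05[1L], gp05_alt = depth$gp05[2L],
        pp05_ref = depth$pp05[1L], pp05_alt = depth$pp05[2L],
        green_ref = depth$green[1L], green_alt = depth$green[2L],
        purple_ref = depth$purple[1L], purple_alt = depth$purple[2L]
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- utils::read.table(
      text = "", col.names = .variant_cols, stringsAsFactors = FALSE
    )
  }
  # chromosome labels "chr1"/"1" -> integer-ish kept as-is; strip "chr"
  out$chrom <- sub("^chr", "", out$chrom)
  suppressWarnings({
    num <- as.integer(out$chrom)
    if (!anyNA(num)) out$chrom <- num
  })
  rownames(out) <- NULL
  out
}

#' Write a variant table as VCF 4.2 or TSV
#'
#' The VCF writer emits one record per site with the four pool samples
#' (`GP05`, `PP05`, `BULK_GREEN`, `BULK_PURPLE`) carrying `GT:AD`; the
#' GT call is a naive presence call (0/0, 1/1, 0/1, or ./. at zero
#' depth). Output is bit-stable for fixed input.
#'
#' @param sites VariantSite data.frame.
#' @param path Output path.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(sites, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  .check_variants(sites)
  if (format == "tsv") {
    utils::write.table(sites, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  gt <- function(ref, alt) {
    ifelse(ref + alt == 0L, "./.",
           ifelse(alt == 0L, "0/0", ifelse(ref == 0L, "1/1", "0/1")))
  }
  fmt <- function(prefix) {
    r <- sites[[paste0(prefix, "_ref")]]
    a <- sites[[paste0(prefix, "_alt")]]
    paste0(gt(r, a), ":", r, ",", a)
  }
  chroms <- unique(sites$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bulkscan",
    sprintf("##contig=<ID=%s>", chroms),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths for the ref and alt alleles\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "GP05", "PP05", "BULK_GREEN", "BULK_PURPLE",
          sep = "\t")
  )
  body <- paste(
    sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE), ".",
    sites$ref, sites$alt, ".", "PASS",
    paste0("TYPE=", sites$site_type), "GT:AD",
    fmt("gp05"), fmt("pp05"), fmt("green"), fmt("purple"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Keep informative sites for association scanning
#'
#' An informative site has parents that are opposite homozygotes (each
#' parent's minor-allele read fraction at most `e_max` and the two
#' parental major alleles differ) and both bulk depths inside
#' `[min_depth, max_depth]`. Sites failing each rule are counted and the
#' removal report attached as attribute `filter_counts`.
#'
#' `max_depth` defaults to 3x the mean bulk depth of the input; the
#' resolved bound is stored as attribute `max_depth_applied` and reused
#' when a previously filtered table is filtered again, so filtering with
#' defaults is idempotent.
#'
#' @param sites VariantSite data.frame.
#' @param min_depth,max_depth Inclusive bulk depth bounds.
#' @param e_max Maximum parental minor-allele read fraction.
#' @return The filtered table, with attributes `filter_counts` and
#'   `max_depth_applied`.
#' @export
filter_informative <- function(sites, min_depth = 10, max_depth = NULL,
                               e_max = 0.1) {
  .check_variants(sites)
  bulk_depth <- cbind(
    sites$green_ref + sites$green_alt,
    sites$purple_ref + sites$purple_alt
  )
  if (is.null(max_depth)) {
    max_depth <- attr(sites, "max_depth_applied") %||%
      ceiling(3 * mean(bulk_depth))
  }
  gp_tot <- sites$gp05_ref + sites$gp05_alt
  pp_tot <- sites$pp05_ref + sites$pp05_alt
  parent_missing <- gp_tot == 0L | pp_tot == 0L
  gp_minor <- pmin(sites$gp05_ref, sites$gp05_alt) / pmax(gp_tot, 1L)
  pp_minor <- pmin(sites$pp05_ref, sites$pp05_alt) / pmax(pp_tot, 1L)
  gp_major_alt <- sites$gp05_alt > sites$gp05_ref
  pp_major_alt <- sites$pp05_alt > sites$pp05_ref
  not_opposite <- !parent_missing &
    (gp_minor > e_max | pp_minor > e_max | gp_major_alt == pp_major_alt)
  bad_depth <- !parent_missing & !not_opposite &
    (bulk_depth[, 1L] < min_depth | bulk_depth[, 1L] > max_depth |
       bulk_depth[, 2L] < min_depth | bulk_depth[, 2L] > max_depth)
  keep <- !(parent_missing | not_opposite | bad_depth)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(
    input = nrow(sites),
    parent_missing = sum(parent_missing),
    parents_not_opposite = sum(not_opposite),
    bulk_depth = sum(bad_depth),
    kept = sum(keep)
  )
  attr(out, "max_depth_applied") <- max_depth
  if (nrow(out) == 0L) warning("no informative sites remain after filtering")
  out
}

#' Sliding-window marker density
#'
#' Counts sites in overlapping windows tiling each chromosome (defaults:
#' 1 Mb windows advanced in 100 kb steps). A site at position p falls in
#' window `[s, s + window - 1]` iff `s <= p <= s + window - 1`; windows
#' start at 1, 1 + step, ... while the window start lies inside the
#' chromosome.
#'
#' @param sites VariantSite data.frame sorted by (chrom, pos).
#' @param window,step Window size and increment in bp.
#' @param chrom_lengths Optional named/indexed chromosome lengths; by
#'   default the maximum observed position per chromosome.
#' @return WindowDensity data.frame: `chrom`, `window_start`,
#'   `window_end`, `n_sites`.
#' @export
window_density <- function(sites, window = 1e6, step = 1e5,
                           chrom_lengths = NULL) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  .check_variants(sites)
  chroms <- if (is.null(chrom_lengths)) {
    unique(sites$chrom)
  } else {
    names(chrom_lengths) %||% seq_along(chrom_lengths)
  }
  out <- lapply(chroms, function(chr) {
    pos <- sort(sites$pos[sites$chrom == chr])
    len <- if (is.null(chrom_lengths)) {
      max(pos)
    } else if (!is.null(names(chrom_lengths))) {
      chrom_lengths[[as.character(chr)]]
    } else {
      chrom_lengths[[as.integer(chr)]]
    }
    starts <- seq(1, len, by = step)
    ends <- starts + window - 1
    n <- findInterval(ends, pos) - findInterval(starts - 1, pos)
    data.frame(
      chrom = chr, window_start = starts, window_end = ends, n_sites = n
    )
  })
  do.call(rbind, out)
}

#' Export window densities as a BED track
#'
#' BED uses 0-based half-open coordinates; the 1-based inclusive windows
#' are converted accordingly. The density is written in the score column.
#'
#' @param windows A [window_density()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  bed <- data.frame(
    chrom = windows$chrom,
    start = format(windows$window_start - 1, scientific = FALSE, trim = TRUE),
    end = format(windows$window_end, scientific = FALSE, trim = TRUE),
    name = "density",
    score = windows$n_sites
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
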
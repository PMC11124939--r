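#' Read a gene annotation from GFF3 (or the TSV mirror)
#'
#' GFF3 files are parsed with rtracklayer; records of type `gene` are
#' kept and the annotation string is taken from the `description`,
#' `Note` or `product` attribute (first available).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A GeneModel data.frame: `gene`, `chrom`, `start`, `end`,
#'   `annotation`.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path)) "gff3" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "chrom", "start", "end", "annotation")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0L) {
      stop("annotation table is missing columns: ",
           paste(miss, collapse = ", "))
    }
    return(tab[, need])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  meta <- S4Vectors::mcols(gr)
  pick <- function(col) {
    if (col %in% names(meta)) as.character(meta[[col]]) else
      rep(NA_character_, length(gr))
  }
  annot <- pick("description")
  for (col in c("Note", "product")) {
    alt <- pick(col)
    annot <- ifelse(is.na(annot) | annot == "", alt, annot)
  }
  chrom <- sub("^chr", "", as.character(GenomicRanges::seqnames(gr)))
  suppressWarnings({
    num <- as.integer(chrom)
    if (!anyNA(num)) chrom <- num
  })
  data.frame(
    gene = as.character(meta$ID %||% meta$Name),
    chrom = chrom,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    annotation = ifelse(is.na(annot), "", annot)
  )
}

#' Write a gene annotation as GFF3
#'
#' @param genes GeneModel data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(genes$start, genes$end),
    type = "gene",
    source = "bulkscan",
    ID = genes$gene,
    Name = genes$gene,
    description = genes$annotation
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Genes overlapping a candidate region
#'
#' Under the default `overlap` rule a gene is reported when its interval
#' shares at least 1 bp with the region (1-based inclusive on both
#' sides); `containment` requires the gene to lie entirely inside.
#'
#' @param genes GeneModel data.frame.
#' @param reg A Region (one or more rows; a gene is reported if it
#'   matches any row).
#' @param rule `"overlap"` or `"containment"`.
#' @return Character vector of gene ids.
#' @export
genes_in_region <- function(genes, reg, rule = c("overlap", "containment")) {
  rule <- match.arg(rule)
  hit <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(reg))) {
    hit <- hit | if (rule == "overlap") {
      genes$chrom == reg$chrom[i] &
        genes$start <= reg$end[i] & genes$end >= reg$start[i]
    } else {
      genes$chrom == reg$chrom[i] &
        genes$start >= reg$start[i] & genes$end <= reg$end[i]
    }
  }
  genes$gene[hit]
}
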
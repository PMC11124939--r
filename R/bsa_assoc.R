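#' Per-site SNP-index of the two bulks and their difference
#'
#' The SNP-index of a bulk is the fraction of its reads carrying the
#' PP05 (purple-parent) allele; the allele is oriented from the parental
#' pools (the PP05 pool's majority allele). `delta` is
#' `index_purple - index_green`: near +1 at a locus where the purple
#' bulk is fixed for the PP05 allele, near 0 away from the trait locus.
#'
#' Sites where a bulk has zero depth get `NA` indices and are flagged
#' `missing`; sites whose parents are not opposite homozygotes cannot be
#' oriented and raise an error (filter with [filter_informative()]
#' first).
#'
#' @param sites VariantSite data.frame of informative sites.
#' @return Data.frame `chrom`, `pos`, `site_type`, `index_green`,
#'   `index_purple`, `delta`, `depth_green`, `depth_purple`, `missing`.
#' @export
snp_index <- function(sites) {
  .check_variants(sites)
  gp_major_alt <- sites$gp05_alt > sites$gp05_ref
  pp_major_alt <- sites$pp05_alt > sites$pp05_ref
  ambiguous <- sites$gp05_alt == sites$gp05_ref |
    sites$pp05_alt == sites$pp05_ref
  unoriented <- ambiguous | gp_major_alt == pp_major_alt
  if (any(unoriented)) {
    stop(
      "cannot orient ", sum(unoriented),
      " site(s): parents are not opposite homozygotes; ",
      "apply filter_informative() first"
    )
  }
  pp_allele_reads <- function(ref, alt) ifelse(pp_major_alt, alt, ref)
  depth_green <- sites$green_ref + sites$green_alt
  depth_purple <- sites$purple_ref + sites$purple_alt
  idx_g <- pp_allele_reads(sites$green_ref, sites$green_alt) / depth_green
  idx_p <- pp_allele_reads(sites$purple_ref, sites$purple_alt) / depth_purple
  idx_g[depth_green == 0L] <- NA_real_
  idx_p[depth_purple == 0L] <- NA_real_
  data.frame(
    chrom = sites$chrom, pos = sites$pos, site_type = sites$site_type,
    index_green = idx_g, index_purple = idx_p,
    delta = idx_p - idx_g,
    depth_green = depth_green, depth_purple = depth_purple,
    missing = depth_green == 0L | depth_purple == 0L
  )
}

#' Per-site Euclidean distance between bulk allele-frequency vectors
#'
#' For a biallelic site with alt-allele read fractions `f_g` (green
#' bulk) and `f_p` (purple bulk),
#' `ED = sqrt((f_g - f_p)^2 + ((1 - f_g) - (1 - f_p))^2)
#'     = sqrt(2) * |f_g - f_p|`,
#' bounded by `[0, sqrt(2)]`. Zero-depth pools give `NA` and are
#' flagged.
#'
#' @param sites VariantSite data.frame.
#' @return Data.frame `chrom`, `pos`, `site_type`, `ed`, `depth_green`,
#'   `depth_purple`, `missing`.
#' @export
ed <- function(sites) {
  .check_variants(sites)
  depth_green <- sites$green_ref + sites$green_alt
  depth_purple <- sites$purple_ref + sites$purple_alt
  f_g <- sites$green_alt / depth_green
  f_p <- sites$purple_alt / depth_purple
  val <- sqrt((f_g - f_p)^2 + ((1 - f_g) - (1 - f_p))^2)
  val[depth_green == 0L | depth_purple == 0L] <- NA_real_
  data.frame(
    chrom = sites$chrom, pos = sites$pos, site_type = sites$site_type,
    ed = val,
    depth_green = depth_green, depth_purple = depth_purple,
    missing = depth_green == 0L | depth_purple == 0L
  )
}

#' Power-transform raw ED values to suppress background noise
#'
#' Raises each ED value to the power `k` (default 5). Away from the
#' trait locus ED is small, so self-multiplication drives the background
#' towards zero while the signal (ED near sqrt(2)) is amplified.
#'
#' @param records An [ed()] table.
#' @param k Power, `k >= 1`.
#' @return The table with an added `ed_k` column; `k` stored as
#'   attribute `k`.
#' @export
ed_power <- function(records, k = 5) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("k must be a single number >= 1")
  }
  records$ed_k <- records$ed^k
  attr(records, "k") <- k
  records
}
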
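#' Simulate pooled sequencing of the four DNA pools
#'
#' Emulates equal-amount DNA mixing and short-read sequencing of the two
#' parental pools (GP05, PP05) and the two extreme bulks. Per site and
#' pool, the true PP05-allele frequency is `sum(genotype codes) /
#' (2 * n_bulk)` (parents are fixed at 0 and 1), the total depth is
#' Poisson(`mean_depth`), and the PP05-allele read count is
#' Binomial(depth, `p * (1 - e) + (1 - p) * e`) with per-read error `e`.
#' The PP05 allele is emitted as the ALT allele.
#'
#' Zero-depth pools are permitted and show up as `(0, 0)` depth pairs.
#'
#' @param pop A [simulate_f2()] population.
#' @param bulks A [build_bulks()] result.
#' @param config Simulation config (defaults to the population's).
#' @param seed Seed for the read draws; defaults to `config$seed + 1` so
#'   the population and read stages use distinct streams.
#' @return A VariantSite data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `site_type` (`SNP`/`InDel`) and per-pool depth pairs
#'   `gp05_ref/alt`, `pp05_ref/alt`, `green_ref/alt`, `purple_ref/alt`.
#' @export
simulate_pool_reads <- function(pop, bulks, config = pop$config,
                                seed = config$seed + 1L) {
  stopifnot(inherits(pop, "bsa_population"))
  withr::with_seed(seed, {
    m <- nrow(pop$markers)
    n_bulk <- length(bulks$bulk_low)
    p_green <- colSums(pop$genotypes[bulks$bulk_low, , drop = FALSE]) /
      (2 * n_bulk)
    p_purple <- colSums(pop$genotypes[bulks$bulk_high, , drop = FALSE]) /
      (2 * n_bulk)
    e <- config$seq_error
    draw_pool <- function(p) {
      depth <- stats::rpois(m, config$mean_depth)
      alt <- stats::rbinom(m, depth, p * (1 - e) + (1 - p) * e)
      list(ref = depth - alt, alt = alt)
    }
    gp <- draw_pool(rep(0, m))
    pp <- draw_pool(rep(1, m))
    green <- draw_pool(p_green)
    purple <- draw_pool(p_purple)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    is_indel <- stats::rbinom(m, 1L, config$indel_frac) == 1L
    alt[is_indel] <- paste0(ref[is_indel], "T")  # 1 bp insertions
    data.frame(
      chrom = pop$markers$chrom,
      pos = pop$markers$pos,
      ref = ref,
      alt = alt,
      site_type = ifelse(is_indel, "InDel", "SNP"),
      gp05_ref = gp$ref, gp05_alt = gp$alt,
      pp05_ref = pp$ref, pp05_alt = pp$alt,
      green_ref = green$ref, green_alt = green$alt,
      purple_ref = purple$ref, purple_alt = purple$alt,
      row.names = NULL
    )
  })
}
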
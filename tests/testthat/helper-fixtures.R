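# Builders for tiny in-code fixtures shared across test files.

# A VariantSite row with sensible defaults: parents opposite homozygotes
# (GP05 = ref, PP05 = alt), bulks at moderate depth.
make_site <- function(chrom = 1, pos = 1000, ref = "A", alt = "T",
                      site_type = "SNP",
                      gp05 = c(20L, 0L), pp05 = c(0L, 20L),
                      green = c(15L, 15L), purple = c(15L, 15L)) {
  data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt, site_type = site_type,
    gp05_ref = gp05[1L], gp05_alt = gp05[2L],
    pp05_ref = pp05[1L], pp05_alt = pp05[2L],
    green_ref = green[1L], green_alt = green[2L],
    purple_ref = purple[1L], purple_alt = purple[2L]
  )
}

make_sites <- function(...) do.call(rbind, list(...))

# A hand-built population object with iid (unlinked) genotypes, for
# pooled-read properties that need unlinked markers.
make_iid_population <- function(n_f2, n_markers, seed = 1,
                                config = sim_config(
                                  n_markers = n_markers, n_f2 = n_f2,
                                  n_bulk = floor(n_f2 / 2), seed = seed
                                )) {
  withr::with_seed(seed, {
    geno <- matrix(
      stats::rbinom(n_f2 * n_markers, 2L, 0.5), n_f2, n_markers
    )
    rownames(geno) <- sprintf("F2_%04d", seq_len(n_f2))
    structure(
      list(
        genotypes = geno,
        markers = data.frame(
          chrom = 1L,
          pos = sort(sample.int(1e8, n_markers))
        ),
        liability = stats::rnorm(n_f2),
        phenotype_class = rep(1L, n_f2),
        qtl = list(chrom = 1L, pos_requested = 1, pos = 1, marker = 1L),
        config = config
      ),
      class = "bsa_population"
    )
  })
}

# marker_genotypes object from an explicit code matrix
make_marker_panel <- function(geno, pos = seq_len(nrow(geno)) * 1e6,
                              chrom = 1, type = "SSR") {
  info <- data.frame(
    marker = sprintf("MK_%03d", seq_len(nrow(geno))),
    chrom = chrom, pos = pos, type = type
  )
  rownames(geno) <- info$marker
  structure(list(info = info, geno = geno), class = "marker_genotypes")
}

# small default config used across tests (fast to simulate)
small_config <- function(seed = 1, ...) {
  sim_config(n_markers = 500L, n_f2 = 240L, seed = seed, ...)
}
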
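#' Rank candidate genes in the final region
#'
#' Annotates every region gene with its differential-expression status
#' and orders the list: significant DEGs first, then decreasing
#' `|log2fc|`, then increasing FDR, ties broken by genomic position.
#' Genes whose annotation matches one of the `keywords` (case
#' insensitive; by default pigment-pathway regulators and enzymes:
#' bHLH/MYB/WD transcription factors, chalcone enzymes, vacuolar
#' transport, RNA processing) are flagged `keyword_hit` — a heuristic
#' note, not a ranking criterion ahead of the expression evidence.
#'
#' Region genes missing from the DEG table are kept with `ns` status;
#' their ids are reported in attribute `unmatched`.
#'
#' @param region_genes Gene ids inside the final region
#'   ([genes_in_region()]).
#' @param degs A [call_degs()] table.
#' @param annotation GeneModel data.frame covering the region genes.
#' @param keywords Annotation keywords to flag.
#' @return A CandidateGene data.frame ordered by rank: `gene`, `chrom`,
#'   `start`, `end`, `annotation`, `direction`, `log2fc`, `fdr`,
#'   `keyword_hit`, `rank`.
#' @export
rank_candidates <- function(region_genes, degs, annotation,
                            keywords = c(
                              "bHLH", "MYB", "WD", "chalcone",
                              "anthocyan", "flavon", "transcription factor",
                              "vacuolar", "vesic", "RNA processing"
                            )) {
  missing_annot <- setdiff(region_genes, annotation$gene)
  if (length(missing_annot) > 0L) {
    stop("region gene(s) absent from the annotation table: ",
         paste(utils::head(missing_annot, 5L), collapse = ", "))
  }
  tab <- annotation[match(region_genes, annotation$gene), , drop = FALSE]
  hit <- match(region_genes, degs$gene)
  unmatched <- region_genes[is.na(hit)]
  tab$direction <- ifelse(is.na(hit), "ns", degs$direction[hit])
  tab$log2fc <- ifelse(is.na(hit), NA_real_, degs$log2fc[hit])
  tab$fdr <- ifelse(is.na(hit), NA_real_, degs$fdr[hit])
  pattern <- paste(keywords, collapse = "|")
  tab$keyword_hit <- grepl(pattern, tab$annotation, ignore.case = TRUE)
  sig <- tab$direction != "ns"
  ord <- order(
    !sig,                                      # significant DEGs first
    -abs(ifelse(is.na(tab$log2fc), 0, tab$log2fc)),
    ifelse(is.na(tab$fdr), 1, tab$fdr),
    !tab$keyword_hit,                          # fallback: annotation
    tab$chrom, tab$start
  )
  out <- tab[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}

#' Run the full simulated pipeline
#'
#' Orchestrates every stage on simulated inputs: F2 population and
#' extreme bulks, pooled reads, informative-site filtering,
#' delta SNP-index and ED association scans (SNP and InDel tracks
#' scanned separately, union-merged per method), simulated null
#' thresholds, region calling and intersection of the two methods,
#' marker co-segregation fine mapping, RNA-seq simulation and
#' differential expression, and the ranked candidate report. All
#' randomness derives from `config$seed`; a fixed seed reproduces every
#' output byte for byte.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, all tables, a JSON
#'   provenance record and a Markdown summary are written there.
#' @param reps Null-simulation replicates for the delta thresholds.
#' @param ci_levels Confidence levels simulated; regions are called at
#'   `ci_level`.
#' @param ci_level Level used for delta region calling (default 0.99).
#' @param k ED power-transform exponent.
#' @param bandwidth_bp Smoother bandwidth.
#' @param gap_bp,min_sites Region-calling parameters.
#' @param n_marker_panel Markers in the fine-mapping panel, spread over
#'   the intersection region.
#' @param n_genes,n_de,log2fc Expression-simulation parameters.
#' @param with_markers,with_expression Disable the fine-mapping or
#'   expression stages; with `with_markers = FALSE` the pipeline stops
#'   after the association scan and reports `status = "partial"`.
#' @return A list: `population`, `bulks`, `sites`, `snp_track`,
#'   `ed_track`, `ci`, `regions` (per method, intersection, refined),
#'   `coseg`, `expression`, `degs`, `candidates`, `provenance`,
#'   `status` (`"complete"` or `"partial"`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         reps = 10000L, ci_levels = c(0.95, 0.99),
                         ci_level = 0.99, k = 5, bandwidth_bp = 2e6,
                         gap_bp = 1e6, min_sites = 10L,
                         n_marker_panel = 20L, n_genes = 2000L,
                         n_de = 100L, log2fc = 2,
                         with_markers = TRUE, with_expression = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  pop <- simulate_f2(config)
  bulks <- build_bulks(pop)
  raw_sites <- simulate_pool_reads(pop, bulks)
  sites <- filter_informative(raw_sites)

  # association scans, SNP and InDel tracks separately per method
  si <- snp_index(sites)
  ed_rec <- ed_power(ed(sites), k = k)
  ci <- simulate_ci(
    depth_grid(pmin(si$depth_green, si$depth_purple)),
    n_bulk = length(bulks$bulk_low), reps = reps,
    levels = ci_levels, seed = config$seed + 10L
  )
  scan_one <- function(records, value, absolute) {
    lapply(split(records, records$site_type), function(part) {
      fit_track(part, value, bandwidth_bp = bandwidth_bp,
                absolute = absolute)
    })
  }
  snp_tracks <- scan_one(si, "delta", absolute = TRUE)
  ed_tracks <- scan_one(ed_rec, "ed_k", absolute = FALSE)
  delta_regions <- union_regions(do.call(rbind, lapply(
    snp_tracks, function(tr) {
      thr <- ci_threshold(ci, pmin(tr$depth_green, tr$depth_purple),
                          level = ci_level)
      call_regions(tr, thr, gap_bp, min_sites, method = "snp_index")
    }
  )), method = "snp_index")
  ed_thr <- ed_threshold(unlist(lapply(ed_tracks, `[[`, "fitted")))
  ed_regions <- union_regions(do.call(rbind, lapply(
    ed_tracks, function(tr) {
      call_regions(tr, ed_thr, gap_bp, min_sites, method = "ed")
    }
  )), method = "ed")
  inter <- intersect_regions(ed_regions, delta_regions)

  result <- list(
    population = pop, bulks = bulks, sites = sites,
    snp_track = do.call(rbind, snp_tracks),
    ed_track = do.call(rbind, ed_tracks),
    ci = ci,
    regions = list(
      snp_index = delta_regions, ed = ed_regions, intersection = inter
    ),
    status = "partial"
  )
  result$provenance <- list(
    package = "bulkscan",
    version = as.character(utils::packageVersion("bulkscan")),
    seed = config$seed,
    parameters = list(
      reps = reps, ci_levels = ci_levels, ci_level = ci_level, k = k,
      bandwidth_bp = bandwidth_bp, gap_bp = gap_bp, min_sites = min_sites,
      ed_threshold = ed_thr
    ),
    config = unclass(config)
  )

  target <- if (nrow(inter) > 0L) {
    inter[which.max(inter$end - inter$start), , drop = FALSE]
  } else {
    NULL
  }
  if (with_markers && !is.null(target)) {
    panel_pos <- seq(target$start, target$end, length.out = n_marker_panel)
    markers <- sample_markers(pop, panel_pos, chrom = target$chrom)
    coseg <- score_cosegregation(markers, bulks$bulk_low, bulks$bulk_high)
    result$markers <- markers
    result$coseg <- coseg
    refined <- tryCatch(refine_interval(coseg, target), error = identity)
    if (inherits(refined, "error")) {
      # no co-segregating marker in the panel: keep the scan region and
      # flag that a denser panel is needed
      result$finemap_note <- conditionMessage(refined)
    } else {
      result$regions$finemap <- refined
      result$status <- "complete"
    }
  }
  if (with_expression) {
    final_region <- result$regions$finemap %||% target
    expr <- simulate_expression(
      config, region = final_region, n_de = n_de, log2fc = log2fc,
      n_genes = n_genes
    )
    fp <- fpkm(expr$counts, expr$lengths)
    kept <- filter_low_expression(fp)
    degs <- call_degs(expr$counts[kept, , drop = FALSE], expr$groups)
    result$expression <- expr
    result$degs <- degs
    if (!is.null(final_region)) {
      region_genes <- genes_in_region(expr$genes, final_region)
      result$candidates <- rank_candidates(region_genes, degs, expr$genes)
    }
  }
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# depth grid for the null-threshold simulation: deciles of the observed
# per-site depths (unique, >= 1)
depth_grid <- function(depths) {
  g <- unique(round(stats::quantile(depths, seq(0, 1, 0.1), names = FALSE)))
  g[g >= 1L]
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(out_dir, name)
  tsv <- function(x, name) {
    utils::write.table(x, p(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_variants(result$sites, p("sites.tsv"), "tsv")
  write_variants(result$sites, p("sites.vcf"), "vcf")
  tsv(result$snp_track, "snp_index_track.tsv")
  tsv(result$ed_track, "ed_track.tsv")
  tsv(as.data.frame(result$ci), "delta_ci.tsv")
  for (name in names(result$regions)) {
    write_regions(result$regions[[name]],
                  p(sprintf("regions_%s.tsv", name)), "tsv")
    write_regions(result$regions[[name]],
                  p(sprintf("regions_%s.bed", name)), "bed")
  }
  if (!is.null(result$markers)) {
    write_marker_genotypes(result$markers, p("markers.tsv"))
    tsv(result$coseg, "cosegregation.tsv")
  }
  if (!is.null(result$expression)) {
    counts <- data.frame(
      gene = rownames(result$expression$counts),
      length = result$expression$lengths,
      result$expression$counts,
      check.names = FALSE
    )
    tsv(counts, "counts.tsv")
    write_annotation(result$expression$genes, p("genes.gff3"))
    tsv(result$degs, "degs.tsv")
  }
  if (!is.null(result$candidates)) tsv(result$candidates, "candidates.tsv")
  jsonlite::write_json(
    result$provenance, p("provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  writeLines(pipeline_summary(result), p("summary.md"))
  invisible(out_dir)
}

pipeline_summary <- function(result) {
  fmt_regions <- function(r) {
    if (nrow(r) == 0L) return("  (none)")
    sprintf("  - chr%s:%s-%s (%.2f Mb, %s sites)",
            r$chrom, format(r$start, big.mark = ",", scientific = FALSE),
            format(r$end, big.mark = ",", scientific = FALSE),
            r$length_mb, r$n_sites)
  }
  lines <- c(
    "# Bulked-segregant scan summary",
    "",
    sprintf("- seed: %d; status: %s", result$provenance$seed, result$status),
    sprintf("- informative sites: %d", nrow(result$sites)),
    sprintf("- ED threshold (median + 3SD of fitted values): %.4g",
            result$provenance$parameters$ed_threshold),
    "",
    "## Regions"
  )
  for (name in names(result$regions)) {
    lines <- c(lines, sprintf("### %s", name),
               fmt_regions(result$regions[[name]]))
  }
  if (!is.null(result$candidates)) {
    top <- utils::head(result$candidates, 8L)
    lines <- c(
      lines, "", "## Top candidates",
      sprintf("  %d. %s (%s; log2FC %.2f; FDR %.3g)%s",
              top$rank, top$gene, top$direction,
              ifelse(is.na(top$log2fc), 0, top$log2fc),
              ifelse(is.na(top$fdr), 1, top$fdr),
              ifelse(top$keyword_hit, " [keyword]", ""))
    )
  }
  lines
}
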
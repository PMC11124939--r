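#' Construct a candidate region
#'
#' A region is a 1-based inclusive chromosome interval tagged with the
#' method that produced it; its length in Mb is `(end - start + 1)/1e6`
#' rounded to 2 decimals.
#'
#' @param chrom Chromosome.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param method Producing method tag (`ed`, `snp_index`,
#'   `intersection`, `finemap`, ...).
#' @param n_sites,peak Optional summary statistics.
#' @return A one-row (or recycled multi-row) Region data.frame.
#' @export
#' @examples
#' region(10, 62600000, 82400000, "intersection")$length_mb  # 19.80
region <- function(chrom, start, end, method = "region",
                   n_sites = NA_integer_, peak = NA_real_) {
  if (any(end < start)) stop("region end before start")
  data.frame(
    chrom = chrom, start = start, end = end, method = method,
    n_sites = n_sites, peak = peak,
    length_mb = round((end - start + 1) / 1e6, 2)
  )
}

empty_regions <- function(method = "region") {
  region(1, 1, 1, method)[0L, , drop = FALSE]
}

#' Call regions above an association threshold
#'
#' Per chromosome, takes maximal runs of consecutive markers whose
#' fitted statistic exceeds its threshold, merges runs separated by less
#' than `gap_bp`, and drops regions supported by fewer than `min_sites`
#' above-threshold markers. Region bounds are the first and last marker
#' positions of the run.
#'
#' @param track A [fit_track()] scan track (or any data.frame with
#'   `chrom`, `pos`, `fitted`).
#' @param threshold Scalar threshold or one value per marker (per-depth
#'   thresholds from [ci_threshold()]).
#' @param gap_bp Merge runs separated by less than this distance.
#' @param min_sites Minimum above-threshold markers per region.
#' @param method Method tag for the output regions.
#' @return A Region data.frame (possibly empty), with the threshold
#'   rule recorded in attribute `threshold`.
#' @export
call_regions <- function(track, threshold, gap_bp = 1e6, min_sites = 10L,
                         method = "scan") {
  stopifnot(all(c("chrom", "pos", "fitted") %in% names(track)))
  thr <- rep_len(threshold, nrow(track))
  above <- !is.na(track$fitted) & track$fitted > thr
  out <- list()
  for (chr in unique(track$chrom)) {
    sel <- which(track$chrom == chr)
    sel <- sel[order(track$pos[sel])]
    a <- above[sel]
    if (!any(a)) next
    r <- rle(a)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    runs <- data.frame(
      start = track$pos[sel][starts_i[r$values]],
      end = track$pos[sel][ends_i[r$values]],
      n = r$lengths[r$values],
      peak = vapply(which(r$values), function(j) {
        max(track$fitted[sel][starts_i[j]:ends_i[j]])
      }, numeric(1L))
    )
    # merge runs closer than gap_bp
    merged <- runs[1L, , drop = FALSE]
    if (nrow(runs) > 1L) {
      for (j in 2L:nrow(runs)) {
        last <- nrow(merged)
        if (runs$start[j] - merged$end[last] < gap_bp) {
          merged$end[last] <- runs$end[j]
          merged$n[last] <- merged$n[last] + runs$n[j]
          merged$peak[last] <- max(merged$peak[last], runs$peak[j])
        } else {
          merged <- rbind(merged, runs[j, ])
        }
      }
    }
    merged <- merged[merged$n >= min_sites, , drop = FALSE]
    if (nrow(merged) > 0L) {
      out[[length(out) + 1L]] <- region(
        chr, merged$start, merged$end, method, merged$n, merged$peak
      )
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else empty_regions(method)
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  res
}

#' Intersect two region lists
#'
#' Computes all pairwise interval intersections per chromosome (1-based
#' inclusive) and reports the total intersected length in Mb at 2
#' decimals (attribute `total_mb`).
#'
#' @param a,b Region data.frames.
#' @param method Tag for the output regions.
#' @return A Region data.frame with attribute `total_mb`.
#' @export
intersect_regions <- function(a, b, method = "intersection") {
  out <- list()
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ra <- a[a$chrom == chr, , drop = FALSE]
    rb <- b[b$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(ra))) {
      s <- pmax(ra$start[i], rb$start)
      e <- pmin(ra$end[i], rb$end)
      keep <- s <= e
      if (any(keep)) {
        out[[length(out) + 1L]] <- region(chr, s[keep], e[keep], method)
      }
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else empty_regions(method)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "total_mb") <- round(sum(res$end - res$start + 1) / 1e6, 2)
  res
}

#' Union-merge a set of regions
#'
#' Merges overlapping or bookended intervals per chromosome; used to
#' combine the SNP and InDel tracks of one method before intersecting
#' with the other method.
#'
#' @param regions A Region data.frame (several lists `rbind`ed).
#' @param method Tag for the merged regions.
#' @return A merged Region data.frame.
#' @export
union_regions <- function(regions, method = "union") {
  if (nrow(regions) == 0L) return(empty_regions(method))
  out <- list()
  for (chr in unique(regions$chrom)) {
    r <- regions[regions$chrom == chr, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    s <- r$start[1L]; e <- r$end[1L]; n <- r$n_sites[1L]
    for (i in seq_len(nrow(r))[-1L]) {
      if (r$start[i] <= e + 1) {
        e <- max(e, r$end[i])
        n <- n + r$n_sites[i]
      } else {
        out[[length(out) + 1L]] <- region(chr, s, e, method, n)
        s <- r$start[i]; e <- r$end[i]; n <- r$n_sites[i]
      }
    }
    out[[length(out) + 1L]] <- region(chr, s, e, method, n)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write regions as TSV (1-based inclusive) or BED (0-based half-open)
#'
#' @param regions Region data.frame.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- regions
    out$start <- format(out$start, scientific = FALSE, trim = TRUE)
    out$end <- format(out$end, scientific = FALSE, trim = TRUE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bed <- data.frame(
      chrom = regions$chrom,
      start = format(regions$start - 1, scientific = FALSE, trim = TRUE),
      end = format(regions$end, scientific = FALSE, trim = TRUE),
      name = regions$method
    )
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
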
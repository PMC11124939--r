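test_that("FPKM follows the definition and is exactly invertible", {
  counts <- matrix(c(10L, 90L, 0L, 500L), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lengths <- c(1000, 2000)
  # force library size 1e6 in sample 1
  counts[2, 1] <- 1e6 - 10
  f <- fpkm(counts, lengths)
  expect_equal(f["g1", "s1"], 10)
  expect_equal(f["g1", "s2"], 0)
  # doubling every count in a sample leaves that sample's FPKM unchanged
  doubled <- counts; doubled[, 2] <- doubled[, 2] * 2L
  expect_equal(fpkm(doubled, lengths)[, 2], f[, 2])
  # conservation: FPKM * length * total / 1e9 sums back to the library size
  totals <- colSums(counts)
  recovered <- colSums(f * lengths) * totals / 1e9
  expect_equal(unname(recovered), unname(totals))
  bad <- counts; bad[, 1] <- 0L
  expect_error(fpkm(bad, lengths), "library size")
  expect_error(fpkm(counts, c(1000)), "length per row")
})

test_that("the low-expression filter keeps any-sample boundary hits", {
  f <- rbind(
    low = c(0.2, 0.5, 0.9),
    boundary = c(0.1, 1.0, 0.3),
    high = c(5, 8, 2)
  )
  kept <- filter_low_expression(f)
  expect_identical(kept, c("boundary", "high"))
  # planted fixture: 7 all-low genes among 100 -> exactly 93 survive
  withr::with_seed(37, {
    mat <- matrix(stats::runif(600, 2, 50), 100, 6,
                  dimnames = list(sprintf("g%03d", 1:100), NULL))
    low_idx <- sample.int(100, 7)
    mat[low_idx, ] <- stats::runif(42, 0, 0.99)
    expect_identical(length(filter_low_expression(mat)), 93L)
    expect_false(any(sprintf("g%03d", low_idx) %in% filter_low_expression(mat)))
  })
})

test_that("identical groups yield no DEG calls and labels flip signs exactly", {
  withr::with_seed(41, {
    base <- matrix(stats::rnbinom(300 * 3, mu = 50, size = 10), 300, 3)
    dup <- cbind(base, base)
    rownames(dup) <- sprintf("g%d", 1:300)
    groups <- rep(c("a", "b"), each = 3)
    degs <- call_degs(dup, groups)
    expect_identical(sum(degs$direction != "ns"), 0L)
    expect_true(all(degs$log2fc == 0))
    # antisymmetry on arbitrary data
    mat <- matrix(stats::rnbinom(300 * 6, mu = 80, size = 5), 300, 6,
                  dimnames = list(sprintf("g%d", 1:300), NULL))
    fwd <- call_degs(mat, groups, "a", "b")
    rev <- call_degs(mat, groups, "b", "a")
    expect_equal(rev$log2fc, -fwd$log2fc)
    expect_equal(rev$pvalue, fwd$pvalue)
  })
  expect_error(call_degs(matrix(1:4, 2, 2), c("a", "b")), "replicates")
})

test_that("planted DE genes are recovered at the stated thresholds", {
  stats <- vapply(1:3, function(s) {
    expr <- simulate_expression(sim_config(seed = 800 + s), n_de = 100L,
                                log2fc = 2, n_genes = 2000L)
    degs <- call_degs(expr$counts, expr$groups)
    called <- degs$gene[degs$direction != "ns"]
    truth <- expr$truth$gene[expr$truth$is_de]
    c(
      sens = length(intersect(called, truth)) / length(truth),
      fdr = if (length(called)) length(setdiff(called, truth)) /
        length(called) else 0
    )
  }, numeric(2L))
  expect_gte(mean(stats["sens", ]), 0.8)
  expect_lte(mean(stats["fdr", ]), 0.1)
})

test_that("relaxing thresholds never removes a reported DEG", {
  expr <- simulate_expression(sim_config(seed = 43), n_de = 50L,
                              n_genes = 800L)
  strict <- call_degs(expr$counts, expr$groups, fdr_max = 0.01, lfc_min = 1)
  looser_fdr <- call_degs(expr$counts, expr$groups, fdr_max = 0.1, lfc_min = 1)
  looser_lfc <- call_degs(expr$counts, expr$groups, fdr_max = 0.01,
                          lfc_min = 0.5)
  hits <- function(d) d$gene[d$direction != "ns"]
  expect_true(all(hits(strict) %in% hits(looser_fdr)))
  expect_true(all(hits(strict) %in% hits(looser_lfc)))
})

test_that("fold-change estimates agree with DESeq2 on the same matrix", {
  suppressMessages(requireNamespace("DESeq2", quietly = TRUE))
  expr <- simulate_expression(sim_config(seed = 47), n_de = 30L,
                              log2fc = 2, n_genes = 300L)
  degs <- call_degs(expr$counts, expr$groups)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    expr$counts,
    S4Vectors::DataFrame(condition = factor(expr$groups,
                                            levels = c("gc", "pc"))),
    ~condition
  )
  res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  expect_gt(stats::cor(degs$log2fc, res$log2FoldChange, use = "complete.obs"),
            0.95)
  # strong effects called by the reference are called here too
  strong <- which(!is.na(res$padj) & res$padj < 1e-6 &
                    abs(res$log2FoldChange) > 1.5)
  expect_gt(mean(degs$direction[strong] != "ns"), 0.9)
})

test_that("replicate correlation flags duplicates, nulls and degenerates", {
  withr::with_seed(53, {
    counts <- matrix(stats::rnbinom(10000 * 2, mu = 100, size = 2), 10000, 2,
                     dimnames = list(NULL, c("a", "b")))
    counts <- cbind(counts, dup = counts[, 1])
    lengths <- rep(1000, 10000)
    rc <- replicate_correlation(counts, lengths)
    r_dup <- rc$r[rc$sample_a == "a" & rc$sample_b == "dup"]
    expect_equal(r_dup, 1.0)
    r_indep <- rc$r[rc$sample_a == "a" & rc$sample_b == "b"]
    expect_lt(abs(r_indep), 0.05)
    const <- cbind(counts[, 1:2], flat = rep(1L, 10000))
    rc2 <- replicate_correlation(const, lengths)
    expect_true(all(rc2$degenerate[rc2$sample_b == "flat"]))
  })
})

test_that("replicates of the same condition correlate strongly", {
  expr <- simulate_expression(sim_config(seed = 59), n_de = 0L,
                              n_genes = 2000L)
  rc <- replicate_correlation(expr$counts, expr$lengths)
  expect_true(all(rc$r > 0.9))
})

test_that("overlap counts partition two gene sets", {
  expect_identical(
    overlap_counts(sprintf("g%d", 1:10), sprintf("g%d", 1:10)),
    list(only_a = 0L, only_b = 0L, both = 10L)
  )
  expect_identical(overlap_counts(c("a", "b"), c("c"))$both, 0L)
  # mirrors the reported shared-expression structure: 1114 common ids
  a <- sprintf("g%05d", 1:1500)
  b <- sprintf("g%05d", 387:1800)
  expect_identical(overlap_counts(a, b)$both, 1114L)
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  uni <- sprintf("g%02d", 1:20)
  res <- term_enrichment(uni[1:5], list(T1 = uni[1:5], all = uni),
                         uni, p_max = 1e-4)
  expect_equal(res$pvalue[res$term == "T1"], 1 / choose(20, 5))
  expect_equal(res$pvalue[res$term == "all"], 1)
  expect_true(res$significant_p[res$term == "T1"])
  expect_error(term_enrichment(c("zz"), list(T1 = uni[1:2]), uni), "universe")
  expect_error(term_enrichment(uni[1], list(), uni), "non-empty")
})

test_that("enrichment p values match a brute-force oracle on small universes", {
  # oracle: explicit combinatorial sum over the overlap distribution
  oracle_p <- function(N, K, n, k) {
    j <- k:min(K, n)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  }
  withr::with_seed(61, {
    for (i in 1:25) {
      N <- sample(5:15, 1L)
      uni <- sprintf("u%02d", seq_len(N))
      K <- sample.int(N, 1L)
      n <- sample.int(N, 1L)
      term <- sample(uni, K)
      selected <- sample(uni, n)
      k <- length(intersect(term, selected))
      res <- term_enrichment(selected, list(t = term), uni)
      expect_equal(res$pvalue, oracle_p(N, K, n, k), tolerance = 1e-12)
      expect_identical(res$n_overlap, k)
    }
  })
})

test_that("Q values never reorder enrichment p values", {
  withr::with_seed(67, {
    uni <- sprintf("u%03d", 1:60)
    for (i in 1:5) {
      terms <- lapply(1:40, function(j) sample(uni, sample(2:20, 1L)))
      names(terms) <- sprintf("t%02d", 1:40)
      res <- term_enrichment(sample(uni, 15), terms, uni)
      ord <- order(res$pvalue)
      expect_true(all(diff(res$qvalue[ord]) >= -1e-15))
      expect_true(all(res$qvalue >= res$pvalue - 1e-15))
    }
  })
})
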
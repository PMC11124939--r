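test_that("SNP-index and delta follow pool read fractions", {
  # hand arithmetic: green (12,8), purple (5,15), PP05 allele = alt
  s <- make_site(green = c(12L, 8L), purple = c(5L, 15L))
  si <- snp_index(s)
  expect_equal(si$index_green, 0.4)
  expect_equal(si$index_purple, 0.75)
  expect_equal(si$delta, 0.35)
  # bulks fixed for opposite alleles
  fixed <- make_site(green = c(30L, 0L), purple = c(0L, 30L))
  sif <- snp_index(fixed)
  expect_equal(c(sif$index_green, sif$index_purple, sif$delta), c(0, 1, 1))
  # identical depth vectors in both bulks -> delta 0
  same <- make_site(green = c(9L, 21L), purple = c(9L, 21L))
  expect_equal(snp_index(same)$delta, 0)
  # PP05 allele = ref when parents are swapped
  swapped <- make_site(gp05 = c(0L, 20L), pp05 = c(20L, 0L),
                       green = c(8L, 12L), purple = c(15L, 5L))
  expect_equal(snp_index(swapped)$delta, 0.75 - 0.4)
})

test_that("sites whose parents are not opposite homozygotes cannot be oriented", {
  bad <- make_site(gp05 = c(10L, 10L))
  expect_error(snp_index(bad), "orient")
})

test_that("zero-depth pools are flagged missing, not fabricated", {
  s <- make_site(green = c(0L, 0L))
  si <- snp_index(s)
  expect_true(si$missing)
  expect_true(is.na(si$delta))
  er <- ed(s)
  expect_true(is.na(er$ed))
})

test_that("ED matches the closed form sqrt(2) * |delta f| to 1e-12", {
  expect_equal(ed(make_site(green = c(10L, 10L), purple = c(7L, 7L)))$ed, 0)
  expect_equal(ed(make_site(green = c(30L, 0L), purple = c(0L, 30L)))$ed,
               sqrt(2), tolerance = 1e-12)
  expect_equal(ed(make_site(green = c(12L, 8L), purple = c(5L, 15L)))$ed,
               sqrt(2) * 0.35, tolerance = 1e-12)
  # property over random depth tables
  withr::with_seed(8, {
    for (i in 1:50) {
      d <- make_site(green = c(sample(0:40, 1), sample(1:40, 1)),
                     purple = c(sample(0:40, 1), sample(1:40, 1)))
      f_g <- d$green_alt / (d$green_ref + d$green_alt)
      f_p <- d$purple_alt / (d$purple_ref + d$purple_alt)
      expect_equal(ed(d)$ed, sqrt(2) * abs(f_g - f_p), tolerance = 1e-12)
    }
  })
})

test_that("statistic bounds hold on simulated data", {
  pop <- simulate_f2(small_config(seed = 51))
  sites <- filter_informative(simulate_pool_reads(pop, build_bulks(pop)))
  si <- snp_index(sites)
  expect_true(all(si$index_green >= 0 & si$index_green <= 1, na.rm = TRUE))
  expect_true(all(si$index_purple >= 0 & si$index_purple <= 1, na.rm = TRUE))
  expect_true(all(abs(si$delta) <= 1, na.rm = TRUE))
  er <- ed(sites)
  expect_true(all(er$ed >= 0 & er$ed <= sqrt(2) + 1e-12, na.rm = TRUE))
})

test_that("the ED power transform is exact self-multiplication", {
  rec <- data.frame(ed = c(1, 0.5, 0))
  expect_equal(ed_power(rec, 5)$ed_k, c(1, 0.03125, 0))
  expect_equal(ed_power(rec, 1)$ed_k, rec$ed)
  expect_error(ed_power(rec, 0.5), "k must")
})

test_that("the distance smoother matches a brute-force kernel oracle", {
  # independent oracle: direct tricube weighted mean / weighted lm
  oracle <- function(pos, val, h, degree = 0L) {
    vapply(pos, function(x0) {
      w <- pmax(1 - (abs(pos - x0) / h)^3, 0)^3
      w[abs(pos - x0) >= h] <- 0
      if (degree == 0L) {
        sum(w * val) / sum(w)
      } else {
        fit <- stats::lm(val ~ I(pos - x0), weights = w)
        unname(stats::coef(fit)[1L])
      }
    }, numeric(1L))
  }
  withr::with_seed(13, {
    for (rep in 1:5) {
      n <- sample(10:50, 1L)
      pos <- sort(stats::runif(n, 1, 50e6))
      val <- stats::rnorm(n)
      h <- stats::runif(1, 2e6, 20e6)
      expect_equal(fit_distance(pos, val, h, degree = 0L),
                   oracle(pos, val, h, 0L), tolerance = 1e-10)
      expect_equal(fit_distance(pos, val, h, degree = 1L),
                   oracle(pos, val, h, 1L), tolerance = 1e-8)
    }
  })
})

test_that("the smoother preserves constants and limits to the global mean", {
  pos <- seq(1e6, 40e6, length.out = 30)
  expect_equal(fit_distance(pos, rep(2.5, 30)), rep(2.5, 30))
  vals <- stats::rnorm(30)
  wide <- fit_distance(pos, vals, bandwidth_bp = 1e12)
  expect_equal(wide, rep(mean(vals), 30), tolerance = 1e-6)
  expect_error(fit_distance(pos, vals, bandwidth_bp = 0), "positive")
  expect_error(fit_distance(pos[1:2], c(NA, NA)), "non-missing")
})

test_that("track fitting never crosses chromosome boundaries", {
  rec <- data.frame(
    chrom = rep(1:2, each = 20),
    pos = rep(seq(1e6, 20e6, length.out = 20), 2),
    delta = rep(c(0, 1), each = 20)
  )
  tr <- fit_track(rec, "delta", bandwidth_bp = 50e6)
  expect_equal(tr$fitted, rep(c(0, 1), each = 20))
})

test_that("missing values are excluded from fitting but still get a fit", {
  pos <- seq(1e6, 20e6, length.out = 20)
  val <- rep(1, 20); val[7] <- NA
  f <- fit_distance(pos, val, 5e6)
  expect_equal(f, rep(1, 20))
})

test_that("median + 3 SD threshold uses the sample standard deviation", {
  expect_equal(ed_threshold(c(1, 2, 3)), 5)
  expect_equal(ed_threshold(rep(4, 10)), 4)
  withr::with_seed(17, {
    for (i in 1:20) {
      v <- stats::rnorm(sample(5:200, 1L))
      expect_equal(ed_threshold(v), median(v) + 3 * sd(v))
      # inserting a value equal to the median leaves the median term fixed
      v2 <- c(v, median(v))
      expect_equal(ed_threshold(v2), median(v) + 3 * sd(v2))
    }
  })
  expect_error(ed_threshold(c(1)), "at least 2")
})

test_that("simulated null thresholds behave like quantiles of |delta|", {
  ci <- simulate_ci(30, n_bulk = 30, reps = 5000, levels = c(0.95, 0.99, 1),
                    seed = 3)
  t95 <- ci$threshold[ci$level == 0.95]
  t99 <- ci$threshold[ci$level == 0.99]
  t100 <- ci$threshold[ci$level == 1]
  expect_true(t95 <= t99 && t99 <= t100)
  expect_error(simulate_ci(30, 30, levels = 1.5), "levels")
  expect_error(simulate_ci(30, 30, reps = 10), "reps")
  expect_error(simulate_ci(0, 30), "depths")
})

test_that("null thresholds match exhaustive enumeration at depth 2, n_bulk 1", {
  # exact null: bulk of 1 F2 plant -> allele count ~ Binomial(2, 1/2);
  # reads ~ Binomial(2, freq); enumerate every (freq_g, freq_p, reads) case
  freqs <- c(0, 0.5, 1)
  pf <- stats::dbinom(0:2, 2, 0.5)
  vals <- c(); probs <- c()
  for (ig in 1:3) for (ip in 1:3) for (rg in 0:2) for (rp in 0:2) {
    p <- pf[ig] * pf[ip] *
      stats::dbinom(rg, 2, freqs[ig]) * stats::dbinom(rp, 2, freqs[ip])
    if (p > 0) {
      vals <- c(vals, abs(rp / 2 - rg / 2))
      probs <- c(probs, p)
    }
  }
  exact_q <- function(level) {
    ord <- order(vals)
    cum <- cumsum(probs[ord])
    vals[ord][which(cum >= level)[1L]]
  }
  ci <- simulate_ci(2, n_bulk = 1, reps = 100000, levels = c(0.95, 0.99),
                    seed = 5)
  expect_lt(abs(ci$threshold[ci$level == 0.95] - exact_q(0.95)), 0.02)
  expect_lt(abs(ci$threshold[ci$level == 0.99] - exact_q(0.99)), 0.02)
})

test_that("null thresholds shrink with depth and bulk size", {
  grid <- seq(10, 100, by = 10)
  ci_d <- simulate_ci(grid, n_bulk = 30, reps = 20000, levels = 0.99, seed = 7)
  expect_true(all(diff(ci_d$threshold) <= 0.005))
  by_bulk <- vapply(c(10, 30, 60, 100), function(nb) {
    simulate_ci(30, n_bulk = nb, reps = 20000, levels = 0.99, seed = 9)$threshold
  }, numeric(1L))
  expect_true(all(diff(by_bulk) <= 0.005))
  # interpolation is clamped and monotone between grid points
  thr <- ci_threshold(ci_d, c(5, 15, 1000), level = 0.99)
  expect_equal(thr[1L], ci_d$threshold[1L])
  expect_equal(thr[3L], ci_d$threshold[10L])
  expect_error(ci_threshold(ci_d, 30, level = 0.5), "not present")
})

test_that("region calling finds runs, merges gaps, drops sparse runs", {
  none <- data.frame(chrom = 1, pos = 1:20 * 1e5, fitted = rep(0, 20))
  expect_identical(nrow(call_regions(none, threshold = 1)), 0L)
  # 50 consecutive markers spanning the printed chromosome-10 interval
  pos <- seq(62600000, 82400000, length.out = 50)
  track <- data.frame(chrom = 10, pos = pos, fitted = 2)
  reg <- call_regions(track, threshold = 1)
  expect_identical(nrow(reg), 1L)
  expect_equal(reg$start, 62600000)
  expect_equal(reg$end, 82400000)
  expect_equal(reg$length_mb, 19.80)
  # two above-threshold runs, split by below-threshold markers 0.5 Mb
  # apart: merged under the default 1 Mb gap rule, separate under 0.4 Mb
  two <- data.frame(
    chrom = 1,
    pos = c(seq(1e6, 2e6, length.out = 12),
            seq(2.1e6, 2.4e6, length.out = 4),
            seq(2.5e6, 3.5e6, length.out = 12)),
    fitted = c(rep(2, 12), rep(0, 4), rep(2, 12))
  )
  merged <- call_regions(two, threshold = 1, gap_bp = 1e6)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$n_sites, 24L)
  apart <- call_regions(two, threshold = 1, gap_bp = 4e5)
  expect_identical(nrow(apart), 2L)
  # runs below min_sites are dropped
  sparse <- call_regions(two, threshold = 1, gap_bp = 4e5, min_sites = 20L)
  expect_identical(nrow(sparse), 0L)
  # per-site thresholds are honoured
  vt <- call_regions(two, threshold = c(rep(3, 16), rep(1, 12)),
                     gap_bp = 4e5, min_sites = 5L)
  expect_identical(nrow(vt), 1L)
  expect_equal(vt$start, 2.5e6)
})

test_that("region intersection reproduces the printed interval arithmetic", {
  a <- region(10, 62600000, 82400000, "ed")
  b <- region(10, 50000000, 82400000, "snp_index")
  out <- intersect_regions(a, b)
  expect_equal(out$start, 62600000)
  expect_equal(out$end, 82400000)
  expect_equal(attr(out, "total_mb"), 19.80)
  # disjoint inputs
  expect_identical(
    nrow(intersect_regions(region(1, 1, 10), region(1, 20, 30))), 0L
  )
  expect_identical(
    nrow(intersect_regions(region(1, 1, 10), region(2, 1, 10))), 0L
  )
})

test_that("region intersection is commutative and idempotent", {
  withr::with_seed(23, {
    for (i in 1:10) {
      mk <- function() {
        s <- sort(sample.int(1e7, 6))
        region(sample(1:2, 3, replace = TRUE),
               s[c(1, 3, 5)], s[c(2, 4, 6)], "x")
      }
      a <- union_regions(mk()); b <- union_regions(mk())
      ab <- intersect_regions(a, b)
      ba <- intersect_regions(b, a)
      cols <- c("chrom", "start", "end")
      expect_equal(ab[cols], ba[cols])
      expect_equal(intersect_regions(a, a)[cols],
                   a[order(a$chrom, a$start), cols],
                   ignore_attr = TRUE)
    }
  })
})

test_that("union-merge combines overlapping and bookended regions", {
  r <- rbind(
    region(1, 100, 200, "snp", n_sites = 5L),
    region(1, 201, 300, "snp", n_sites = 4L),  # bookended
    region(1, 250, 400, "indel", n_sites = 3L),
    region(2, 100, 150, "snp", n_sites = 2L)
  )
  u <- union_regions(r, method = "snp_index")
  expect_identical(nrow(u), 2L)
  expect_equal(u$end[1L], 400)
  expect_identical(u$n_sites[1L], 12L)
  expect_identical(nrow(union_regions(r[0L, ])), 0L)
})
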
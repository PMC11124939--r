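---
title: "Methods: bulked-segregant association with RNA-seq co-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked-segregant association with RNA-seq co-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkscan)
```

## The problem and the model

`bulkscan` localizes the gene behind an ordinal trait — the motivating
case is sepal color in an eggplant F2 cross between a purple-sepal
inbred (PP05) and a green-sepal inbred (GP05) — by bulked segregant
analysis sequencing (BSA-seq) plus an RNA-seq co-analysis. Two DNA
pools are built from the phenotypic extremes of the F2 (30 green and 30
purple plants), sequenced together with the two parents, and scanned
for loci where the pools' allele frequencies diverge.

Two per-site statistics are computed from the pooled allele depths:

* **SNP-index / delta.** The SNP-index of a bulk at a site is the
  fraction of its reads carrying the PP05 allele (oriented from the
  parental pools). `delta = index_purple - index_green` is near 0 at
  unlinked loci and near ±1 at the causal locus.
* **Euclidean distance (ED).** With alt-allele read fractions `f_g`
  and `f_p` in the two bulks, `ED = sqrt(2) * |f_g - f_p|` for a
  biallelic site, bounded by `[0, sqrt(2)]`. Raw ED is raised to the
  power `k` (default 5): background values, being below 1, collapse
  toward zero while the near-maximal signal survives. The phrase used
  for this step in ED-based BSA pipelines is de-noising by
  self-multiplication; `k = 5` is the common choice and is
  configurable.

Both statistics are smoothed along each chromosome and thresholded;
regions above threshold are called per method, and the final scan
region is the *intersection* of the two methods' regions. InDel and
SNP sites travel through the identical statistic path, are scanned as
separate tracks, and each method's tracks are union-merged before the
intersection.

## Smoothing: the distance-weighted fit

The per-site statistics are fitted by a tricube-kernel local
regression on physical distance (`fit_distance()`): at evaluation
position $x_0$, sites within bandwidth $h$ get weight
$(1-(d/h)^3)^3$ and a weighted constant (default) or weighted line is
fitted. Defaults: $h = 2$ Mb, local constant. Smoothing never crosses
chromosome boundaries; sites with a zero-depth pool are excluded from
fitting but still receive a fitted value; a position with no
non-missing neighbour falls back to the nearest non-missing value.
The delta track is smoothed on $|delta|$ (two-sided calling; the
orientation of the trait-increasing allele is known from the parents,
but symmetric calling matches the symmetric confidence construction —
a one-sided mode is available via the unsigned records).

## Thresholds

* **Delta:** simulation-based confidence thresholds
  (`simulate_ci()`). The null model draws each bulk's allele count
  from Binomial(2·n_bulk, 1/2) — n_bulk unselected F2 plants, two
  alleles each — then reads from Binomial(depth, frequency), and takes
  the level-L quantile of |delta| per depth. Thresholds are computed
  on a decile grid of observed per-site depths and linearly
  interpolated; a site is looked up at the *minimum* of its two bulk
  depths (the conservative choice; the spec convention of one depth
  per site leaves this open). Region calling defaults to the 99%
  level; 95% is also simulated.
* **ED:** the genome-wide median + 3 sample standard deviations
  (denominator n−1) of the fitted values. The published value of such
  a threshold is dataset-specific; the *rule* is what the package
  implements.

Regions are maximal runs of consecutive markers with fitted value
above threshold; runs separated by less than 1 Mb are merged; runs
with fewer than 10 above-threshold markers are dropped. Region bounds
are marker positions, not window edges. All defaults are configurable
and recorded in the provenance output.

## Fine mapping and the RNA-seq stage

Markers designed inside the scan region (SSR/CAPS in the motivating
study; genotype codes here) are scored for co-segregation in the
bulked plants: under the default additive model the green extremes
must be GP05 homozygotes and the purple extremes PP05 homozygotes;
any violation is a recombinant and co-segregation means *zero*
recombinants — the strict reading of co-segregation, since no
tolerance is published. Missing genotypes are excluded rather than
imputed; markers scored in under 80% of the bulked plants are flagged
low-confidence. The refined interval spans the outermost
co-segregating markers, inclusive.

The expression stage computes FPKM
(`counts * 1e9 / (length * library size)`), drops genes with FPKM < 1
in *all* samples (the boundary value is kept), and calls DEGs at
FDR < 0.01 and |log2FC| > 1. The reference analysis used DESeq2;
re-implementing it verbatim is out of scope, so a declared lightweight
negative-binomial Wald test stands in: median-of-ratios normalization,
pseudocount 0.5 on the group means for the fold change, per-gene
method-of-moments dispersion pooled over the two groups (floored at
1e-8), a delta-method Wald z on the log2 fold change, and BH
correction. Its contract is parameter recovery on synthetic data
(sensitivity ≥ 0.8, empirical FDR ≤ 0.1 on 100 planted two-fold DE
genes among 2000, 3 vs 3), not DESeq2-identical numbers; a test
checks concordance with DESeq2 on a shared matrix. Hypergeometric
term enrichment (upper tail, BH Q across terms) is provided as a
generic stage over user-supplied term maps, with conventional flags at
p ≤ 1e-4 and Q ≤ 0.05; the enrichment background defaults to the
genes surviving the FPKM filter.

Candidates are the genes overlapping the final (refined) region by at
least 1 bp — containment is available by flag; the 1 bp rule is the
default because the published region-gene criterion is unstated —
ranked by DEG evidence (significant first, then |log2FC| decreasing,
then FDR, ties by position). Annotation keyword matching
(bHLH/MYB/WD, chalcone, vacuolar transport, RNA processing, ...) only
*flags* genes: it is an explicitly heuristic stand-in for the manual
curation that produces published candidate shortlists.

## The simulated world

`sim_config()` defaults state the world the pipeline targets:

| parameter | default | why |
|---|---|---|
| genome | 1 chromosome × 100 Mb | the scan's target is a single-chromosome locus |
| markers | 10,000 biallelic sites | desk-scale stand-in for millions of resequencing markers |
| map | Haldane, 1 cM/Mb, no interference | standard default; unstated in the source design |
| F2 size | 240 | the motivating population size |
| major locus | chr1:78 Mb, a = 3, d = 0, σ = 0.5 | single additive locus; the headline region is one locus on one chromosome (an optional second locus is available because the prior genetic model had two major genes) |
| phenotype classes | quintiles of the null liability | five ordinal color classes; only classes 1 and 5 feed bulks |
| bulks | 30 + 30, equal allele weight | equal-amount DNA mixing; no pipetting-noise term |
| pools | Poisson depth 30×, per-read error 0.001 | typical short-read design; parents are p ∈ {0, 1} |
| site types | 11% InDels | the observed InDel:SNP marker ratio in comparable resequencing sets |
| RNA-seq | 3 vs 3, NB dispersion 0.05, log-normal means (median 100) | inbred-line biological replicates |

With a = 3 and σ = 0.5 the liability separation is six residual SDs,
so the extreme classes are almost purely the two homozygotes and the
bulks are effectively fixed — matching a trait clean enough to bulk
on. Class thresholds are quintiles of the *null* liability
distribution so that, with no locus, the five classes are equally
likely; configs whose extreme classes are empty in expectation are
rejected.

What the generator does **not** emulate: read-level errors beyond a
symmetric per-read flip, mapping artifacts, polygenic background
beyond Gaussian noise, segregation distortion, pipetting noise in pool
construction, and LD structure other than the Haldane map. A green
recovery test therefore establishes correctness of the statistics and
plumbing under a clean major-gene world, not robustness to real-data
pathologies.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (VCF convention); BED
  exports convert to 0-based half-open. Region lengths are
  `(end − start + 1)/1e6` Mb, rounded to 2 decimals.
* Depth bounds for informative sites default to [10, 3× mean bulk
  depth]; the resolved upper bound is stored on the filtered table so
  re-filtering with defaults is idempotent. Multiallelic records are
  dropped by default (`multiallelic = "split"` splits them).
* Zero-depth pools are permitted, flagged, and excluded from fitting.
* The smoother guards a degenerate weighted design (all weight at one
  position) by falling back to the local constant.
* All simulator stages are pure functions of (inputs, seed); the
  pipeline derives per-stage seeds from the config seed by fixed
  offsets, and a fixed seed reproduces every output file byte for
  byte.

## Known limitations

* On a *single*-chromosome genome a strong locus leaves most loci in
  partial linkage, so the ED signal inflates both the genome-wide
  median and the SD of the fitted values; the median+3SD threshold can
  then sit marginally above the ED peak and occasionally yield no ED
  region at all. With a multi-chromosome genome (the realistic case)
  the background is dominated by unlinked chromosomes and the rule
  behaves. Conversely, on locus-free data at desk-scale marker density
  the fitted ED field is read-noise dominated and exceeds median+3SD
  somewhere on most chromosomes — harmless in practice because the
  excursions are orders of magnitude below a real signal and vanish in
  the intersection with the delta regions, but a reminder that the
  rule is not a familywise error control at low marker density.
* The co-segregation screen assumes the bulked plants' marker
  genotypes are trustworthy single-plant calls; genotyping error is
  not modeled and one miscalled plant destroys a marker's
  co-segregation under the zero-tolerance rule.
* The NB Wald DEG caller is anticonservative for genes whose sample
  variance underestimates the true dispersion (3 replicates); the
  |log2FC| > 1 requirement absorbs most of this in practice, as the
  null-calibration test shows.
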
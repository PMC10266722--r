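---
title: "Promoter chromatin profiling: models, conventions and design choices"
author: "cutacProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter chromatin profiling: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutacProfiler)
```

## What the package computes

Tethered-tagmentation assays (CUT&Tag and its accessibility variant CUTAC)
produce paired-end fragment libraries whose genomic pileup reports where a
chromatin factor sits or where chromatin is accessible. This package covers
the downstream arithmetic for promoter-centric analyses of such data under
drug perturbations:

1. **Calibrated coverage tracks.** Per-base pileup of whole fragments, then
   one of two calibrations. *Spike calibration* multiplies a sample's pileup
   by `spikeConstant / spikeCount` (default constant 10,000), where
   `spikeCount` is the number of fragments mapping to a spike-in genome
   carried through the experiment; this makes absolute signal comparable
   across samples. *Normalized counts* rescale the per-base fraction of
   total counts by the reference length, so a uniformly distributed library
   reads exactly 1 at every base; this normalizes out depth within a sample.
2. **TSS-anchored matrices.** Promoters x 10-bp bins of track signal over a
   window around the TSS (default ±2,500 bp for heatmaps, −100/+500 bp for
   promoter-proximal summaries), oriented so bin order always runs upstream
   to downstream in the transcriptional sense. K-means clustering of rows
   groups promoters by accessibility profile.
3. **Promoter spacing.** Each promoter's nearest *upstream* neighbor
   (relative to its own strand), the TSS-to-TSS distance, and the
   divergent/tandem orientation call from strand equality.
4. **Distance statistics.** The decile moving median: promoters are ranked
   by inter-promoter distance and a centered window of one tenth of the
   promoter set slides along the ranking, pairing the window median of
   distances with the window median of signal. Plus threshold-stratified
   group medians with Mann–Whitney comparisons, upstream torsion sums with
   a 64-SD outlier filter, and switch-point localization between two
   curves.
5. **Differential profiles.** Per-bin treated/control fold-change ratios,
   split by orientation and stratified by expression quintiles.

## Coordinate and windowing conventions

All text formats (BED, bedGraph, TSV) are 0-based half-open; in-memory
`GRanges`/`IRanges` follow the Bioconductor 1-based closed convention, and
the conversion happens exactly once, in the readers and writers.

The promoter anchor is the TSS base itself. A window of `upstream`/
`downstream` bp covers `[TSS - upstream, TSS + downstream)` in transcription
orientation; for minus-strand promoters "downstream" runs toward smaller
coordinates, and matrix rows are reversed at construction so that bin 1 is
always the most upstream bin. The upstream torsion window `[TSS - w, TSS)`
excludes the TSS base.

**Edge policy.** Windows truncated by a chromosome end contribute only their
covered bases; bins that fall entirely off the end are recorded as `NA` and
excluded from means. This mirrors how deepTools-style tools handle edge
regions; the alternative (dropping edge promoters entirely) would silently
change denominators downstream.

**Ties.** Two upstream promoters can be equidistant only when they share a
TSS on opposite strands; the opposite-strand one is chosen (the only choice
under which the head-to-head reading is consistent), then the
lexicographically smaller ID. Distance-ranking ties in the moving median are
broken by promoter ID. Both rules exist purely for determinism.

## The decile moving median

For `n` promoters the window is `floor(n/10)`, forced odd by subtracting 1
when even so that the focal promoter carries two equal half-windows: for a
16,972-promoter catalogue the window is 1,697 = 1 + 848 + 848. Positions
without a full window are dropped rather than padded — shrinking the window
near the edges would mix statistics of different variance into one curve.
The signal statistic is the median for accessibility data and the mean for
torsion data; both are exposed via `statistic=`.

The switch point between two curves is the largest distance of the longest
suffix (toward small distances) on which the first curve exceeds the second
at every point. This suffix-dominance rule deliberately avoids fitting a
changepoint model: the question it answers is "below what spacing is the
treated curve consistently above control", nothing more.

## The outlier filter

`filterOutliers()` is a single pass: mean and SD are computed once from the
full input, and values strictly more than `thresholdSds` (default 64) SDs
above the mean are removed. The threshold is intentionally extreme — genomic
signal is heavy-tailed, and the filter exists to drop catastrophic
artifacts, not to trim the tail. Because a gross outlier inflates the very
SD it is measured against, the function also accepts an externally supplied
`center`/`scale` pair for the case where reference statistics are known
independently of the contaminated sample; the practical difference is shown
in the tests.

## K-means clustering

`kmeansPromoters()` runs standard Euclidean k-means (`stats::kmeans`, 10
random restarts, best inertia) and then relabels clusters `I`, `II`, ... by
descending raw-scale mean signal, making cluster names stable across seeds
and datasets. Rows are `log1p`-scaled before clustering by default: coverage
noise is multiplicative, so on the raw scale the scatter within a
high-signal cluster exceeds the separation between low-signal clusters and
k-means splits the top cluster instead of separating the bottom ones. The
raw scale remains available via `transform = "none"`. One dataset's
assignment can be applied to another dataset's matrix by promoter ID with
`applyClusters()`, which reorders rows without touching values.

## Fold-change profiles and quintiles

Fold change is the ratio of per-bin means over a promoter subset
(treated over control), with no pseudocount: a zero control bin yields `NA`
rather than an arbitrary finite value, because the upstream calibrations
make zero a meaningful observation. Expression quintiles sort genes in
descending order (ties by ID) and cut into five contiguous blocks, the
remainder going to the top quintiles; `log10(x + 1)` is a display transform
only and never affects ranking.

## The synthetic-data generator

The generator exists so every downstream stage has a test surface with
known truth. It emulates:

- **Promoter tables**: gaps drawn from a configurable spacing law. The
  default is lognormal with median 1,300 bp and `sdlog` 1, putting roughly
  40% of promoters within 1 kb of their upstream neighbor — a realistic
  density for a compact metazoan genome; the law is a parameter because
  real promoter catalogues differ. Strands follow a Markov rule (flip with
  probability `divergentFraction`), which makes the realized divergent
  fraction among annotated pairs match the request; the first promoter per
  chromosome is placed on the minus strand so a fully divergent request
  yields head-to-head geometry deterministically.
- **Fragment sets**: per-promoter expected counts proportional to
  `baselineRate x classRates[class] x boost`, where the boost applies to
  divergent promoters closer than `distanceCutoff` to their upstream
  neighbor. Counts are negative-binomial (dispersion 0.2 by default —
  overdispersion keeps rank tests honest), fragment lengths uniform in
  [50, 300] bp (nucleosomal/subnucleosomal), midpoints normal around the
  TSS shifted 150 bp downstream, plus a 5% uniform background. The spike
  count is carried verbatim. `accessibilityGain()` converts a planted boost
  into a depth-consistent spike count, so calibrated tracks show unboosted
  promoters at control level and boosted promoters elevated — the way a
  genuine accessibility gain presents under spike calibration.
- **Expression tables**: lognormal per orientation group with requested
  group medians (defaults 210.3 divergent / 34.5 tandem, the observed
  contrast for fly promoter catalogues).
- **Torsion tracks**: reads piling into the 200 bp upstream of each TSS,
  enriched at closely spaced promoters.

What it does **not** emulate: sequence content (no G-quadruplex motifs, no
mappability structure), PCR duplication, replicate-level batch effects, or
any pharmacology — a "drug" here is exactly a planted rate change. Passing
tests therefore demonstrate that the arithmetic recovers planted structure
under realistic noise, not that the biology of any particular drug is
reproduced.

Two geometric facts about the generator matter for interpreting tests.
Upstream torsion windows of promoters closer than ~400 bp overlap the
partner's read cloud, so even a null torsion track shows a weak
distance–signal association at very close pairs; the null test conditions
on non-overlapping windows. Likewise, planted cluster classes are only
identifiable from TSS windows when promoters are spaced further apart than
the window plus fragment cloud; the class-recovery test uses an ~8 kb
spacing law for that reason.

## Problem sizes and determinism

Every generator and the k-means step take explicit integer seeds, and
identical seeds give identical outputs (asserted in the tests). The test
suite and the demo run at deliberately moderate sizes — oracle checks use
genomes up to 10 kb against per-base brute-force loops; planted-effect
recovery uses 5,000 promoters across 20 seeds; the demo uses 2,000
promoters and four conditions — sizes at which every statistic is already
stable while the whole suite runs in about a minute.

## Pipeline

`runPipeline()` drives the stages from a single YAML config (sample table
with spike counts, chromosome sizes, promoter BED, optional expression and
torsion inputs, parameters). Stage outputs are files, not in-memory
handoffs, so stages are independently inspectable and a `summary.json`
records every parameter and input/output checksum; reruns with the same
seeds produce identical checksums. `demoSynthetic(seed)` generates a full
synthetic dataset — control, a no-effect drug, a mild booster, and a strong
(3x below 1 kb) divergent-close booster — and runs everything:

```{r, eval = FALSE}
summary <- demoSynthetic(seed = 1, outDir = "demo_run")
```

## Known limitations

- Nearest-neighbor search never crosses chromosome boundaries, and
  promoters without an upstream neighbor are excluded from
  distance-stratified analyses rather than given infinite distance.
- Whole-fragment pileup only; cut-site or midpoint counting would need a
  new mode.
- The Mann–Whitney test is a package decision for median-framed
  comparisons; no multiple-testing correction is applied across strata or
  conditions.
- bigwig export is a convenience wrapper; all analysis I/O is plain-text
  bedGraph/BED/TSV.
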
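# cutacProfiler

Promoter-centric downstream analysis of tethered-tagmentation chromatin
profiling data (CUT&Tag / CUTAC), built for studies that ask how a
perturbation — e.g. an intercalating drug — changes chromatin accessibility
as a function of promoter spacing, orientation and expression.

Starting from per-sample fragment intervals (BED) and spike-in fragment
counts, the package computes:

- **Calibrated coverage tracks** — per-base whole-fragment pileup, scaled
  either by the spike-in factor `10,000 / n_spike` (cross-sample
  comparable) or as normalized counts, the per-base fraction of total
  counts times the reference length `L`:
  `v(x) = raw(x) / Σ raw · L`, so uniform coverage reads 1 everywhere.
- **TSS-anchored matrices** — promoters × 10-bp bins, strand-oriented,
  with k-means clustering of promoters (clusters relabeled I, II, … by
  descending signal) and mean/fold-change profiles.
- **Promoter spacing** — for each promoter, the nearest *upstream*
  neighbor on its own strand's sense, the TSS-to-TSS distance `d`, and the
  orientation call: opposite-strand neighbor ⇒ *divergent* (head-to-head),
  same strand ⇒ *tandem*.
- **Distance statistics** — the decile moving median: rank promoters by
  `d`, slide a centered window of `floor(n/10)` promoters (forced odd, so
  1,697 = 848 + 1 + 848 for a 16,972-promoter catalogue) and pair the
  window median of distances with the window median of signal; plus
  2-kb-threshold group medians with Mann–Whitney comparisons, 200-bp
  upstream torsion sums with a 64-SD outlier filter, and switch-point
  localization between curves.
- **Differential profiles** — per-bin drug/control ratios (linear or
  log2), split by orientation and stratified by expression quintiles.

A seeded synthetic-data module generates promoter tables, fragment sets
with plantable effects (divergent-close accessibility boosts, three-class
cluster structure), expression tables and torsion tracks, so the entire
pipeline is testable without sequencing data.

## Worked example

The one-command demo generates a 2,000-promoter genome with four
conditions — control, a no-effect drug, a mild booster, and a strong
booster planting 3× accessibility at divergent promoters closer than
1 kb — and runs the full pipeline:

```r
library(cutacProfiler)
summary <- demoSynthetic(seed = 1, outDir = "demo_run")
cmp <- jsonlite::read_json("demo_run/results/distance_comparisons.json",
                           simplifyVector = TRUE)
str(cmp$acla_like)
#> $ medians        : close: 3961,  far: 2241
#> $ control_medians: close: 2664,  far: 2108.5
#> $ n              : close: 1338,  far: 662
#> $ p_value        : close: 3.59e-12,  far: 0.786
#> $ switch_point   : 1114
```

Reading: promoters closer than 2 kb to their upstream neighbor gained
accessibility under the boosted condition (median promoter-proximal sum
3961 vs 2664 in control, Mann–Whitney p ≈ 4e-12), distant promoters did
not (2241 vs 2108.5, p = 0.79), and the boosted condition's moving-median
curve starts dominating the control's at 1,114 bp — recovering the planted
1-kb cutoff. The no-effect condition shows no close-stratum shift
(p = 0.54). Per-bin fold-change profiles split by orientation land where
the planting puts them (mean ratio 1.86 at divergent promoters vs 1.08 at
tandem, seed 1).

Each run directory also contains the calibrated bedGraph tracks, the
gzipped TSS matrices, cluster assignments (here 429 / 567 / 1,004 promoters
in clusters I/II/III), the spacing annotation TSV, torsion outlier report
and decile curves, and a `summary.json` of parameters and checksums.

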
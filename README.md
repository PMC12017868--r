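# periLoop

Quantitative analytics for cohesin- and Scc2-dependent chromosome folding
in budding yeast: spike-in calibrated ChIP-seq quantification and
Micro-C/Hi-C contact-map analysis, with a synthetic dual-genome data
generator that provides known ground truth for every stage.

## Who it is for

Chromosome-biology groups comparing protein occupancy and DNA loop
architecture across strains or depletion conditions — e.g. asking whether
a regulator deletion raises the Scc2/Scc1 occupancy ratio at cohesin
binding sites, or whether pericentromeric DNA loops grow from a few tens
of kb to >100 kb when cohesin's ATPase activator stays bound.

## What it computes

**Calibrated ChIP-seq.** With reads mapped to the target genome
(*S. cerevisiae*) and a spike-in genome (*C. glabrata*) in both ChIP and
input fractions, the occupancy ratio is

    OR = (ChIP_Scer x input_Cgla) / (input_Scer x ChIP_Cgla)

and the normalization factor of a sample against a declared control is
`NF = OR_treated / OR_control`.  A ChIP track is rescaled so its
genome-wide total equals `1,500,000 x NF`, the input to `1,500,000`, and
the normalized fold-enrichment (nFE) of each 100-bp bin is the scaled
ChIP/input ratio.  Peaks are maximal bin runs with `nFE >= 2.0`.
Site-level statistics: per-site window means, quartile groups Q1–Q4 by
increasing nFE, ratio analysis normalized to the control median,
aggregate profiles with 95% confidence bands, and centromere-distance
annotation with a 5-kb exclusion radius.

**Contact maps.** Cis matrices (COO triplet text) are balanced by
iterative correction; per-arm expected profiles give observed/expected
ratios; contact-versus-distance curves and their log-log derivative
characterize decay; insulation scores (5- and 10-kb windows) mark
boundaries; a simplified HICCUPS-style caller tests every pixel against
donut, lower-left, horizontal and vertical local backgrounds with Poisson
statistics at BH-FDR 0.1, merging enriched pixels within 2,500 bp; APA
pile-ups average observed/expected in 20x20-kb windows (central 3x3
score); loops are classified as centromere-originated or cohesin-anchored
and cohesin sites are flagged as loop-anchor sites.

**Gene context.** Genes flanking each cohesin site are labeled
CEN-oriented (centromere-distal, transcribed toward the centromere) or
TEL-oriented (centromere-proximal, transcribed away), and anchor versus
non-anchor groups are compared by two-sided Mann-Whitney U tests (exact
for small untied samples).

**Synthetic data.** `simulateChipCounts()` draws dual-genome multinomial
read counts at configured mixing ratios, bound fractions and site
enrichments; `simulateContactMap()` draws Poisson contacts around a
power-law decay with injected loop dots, domain blocks and centromere
attenuation.  `scenarioPreset()` bundles a wild-type-like condition
(dense ~20-kb cohesin-cohesin loops, low arm-site Scc2) and a
wpl1/eco1-loss-like condition (sparse 50–110-kb centromere-anchored
loops, Scc2/Scc1 fold 2.53) with a full ground-truth manifest.

## Worked example

```r
library(periLoop)
wt  <- runPipeline("wt_like",        seed = 1)
mut <- runPipeline("wpl1_eco1_like", seed = 1)
cmp <- compareConditions(wt, mut)
cmp[cmp$metric %in% c("scc2_peak_count", "ratio_median_fold", "loop_count",
                      "cen_loop_count", "cen_loop_mean_length",
                      "anchor_count", "apa_central_score"), ]
```

```
               metric        a         b      delta   fold
      scc2_peak_count    5.000    37.000    32.0000 7.4000
    ratio_median_fold    1.000     2.575     1.5754 2.5754
           loop_count   37.000    15.000   -22.0000 0.4054
       cen_loop_count    4.000    15.000    11.0000 3.7500
 cen_loop_mean_length 9000.000 81200.000 72200.0000 9.0222
         anchor_count    4.000    14.000    10.0000 3.5000
    apa_central_score    2.677     3.535     0.8576 1.3203
```

Column `a` is the wild-type-like run, `b` the mutant-like run.  The
mutant-like condition gains Scc2 peaks at cohesin sites (5 → 37), its
Scc2/Scc1 median ratio fold recovers the injected 2.53 (2.58 here),
called loops become fewer but much longer — centromere-originated loops
average 81 kb versus 9 kb — and the cohesin sites flagged as loop anchors
(14) are exactly the sites the generator wired to the centromere.  Each
report also carries the full loop table, site table, insulation profiles
and calibration numbers (`wt$loops$table`, `wt$siteTable`, ...).

## Layout

```
R/                 S4 classes (GenomeAnnotation, BinnedTrack, ContactMap),
                   I/O, simulators, calibration, site/contact/gene analytics,
                   pipeline
tests/testthat/    unit, property and acceptance suites (all synthetic)
scripts/           acceptance.R
vignettes/         methods vignette (model, parameters, design choices)
```
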
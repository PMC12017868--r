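---
title: "periLoop: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{periLoop: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

periLoop quantifies two complementary readouts of cohesin biology in
budding yeast: how much of a protein sits at a genomic site (spike-in
calibrated ChIP-seq) and how chromatin folds around centromeres (cis
contact maps).  This vignette explains the models behind each stage, the
parameters that matter, the numerical choices, and what validation on
synthetic data does and does not demonstrate.

## Spike-in calibration

Cross-species spike-in normalization rests on one assumption: target and
spike-in chromatin are mixed at a fixed cell-equivalent ratio before
immunoprecipitation, so the spike-in read counts act as an internal
yardstick shared by the ChIP and input fractions.  The occupancy ratio

$$\mathrm{OR} = \frac{\mathrm{ChIP}_{Scer}\times \mathrm{input}_{Cgla}}
                     {\mathrm{input}_{Scer}\times \mathrm{ChIP}_{Cgla}}$$

is invariant to the sequencing depth of either fraction (both a ChIP- and
an input-side rescaling cancel), which the test suite asserts directly.
The normalization factor of a sample is its OR divided by the OR of a
declared control, so NF is 1 for the control itself and chains
multiplicatively across samples.

An nFE track scales the raw ChIP vector to a genome-wide total of
$1{,}500{,}000 \times \mathrm{NF}$ and the input vector to $1{,}500{,}000$,
then takes the per-bin ratio.  The input scaling constant is applied
symmetrically (an assumption; only the ChIP-side constant is part of the
published semantics).  Two policies are deliberate:

* **No pseudocounts.**  A bin with fewer raw input reads than
  `minInputReads` (default 1) is masked, not smoothed; smoothing invents
  enrichment where the input has no information.
* **No pre-threshold smoothing.**  Whether the upstream binning tool
  smooths internally is undocumented; the package default is off, with a
  running-mean window available (`smoothBins`).

Peak calling is a threshold rule, not a model: maximal runs of unmasked
bins with nFE at or above 2.0 (the threshold used for the real data),
with configurable merge gap (default 0 bins) and minimum width (default
1 bin), and leftmost-maximum summits for determinism.  Lowering the
threshold can only grow peak territory; this monotonicity is tested as a
property.

"nFE at a site" is reduced to the mean over a 400-bp window centered on
the site summit.  The window is a package choice — the published figures
do not state the reduction — and is configurable; boxplot-style
statistics in the pipeline use the same reduction so comparisons stay
internally consistent.  Quartile groups sort sites ascending by value
(ties broken by coordinate) and split them into four contiguous groups,
remainders assigned to the lower quartiles, so a 10-site set splits
3/3/2/2 and Q4 always holds the highest values.  Ratio analysis divides
each site's numerator/denominator ratio by the median control ratio and
reports the median normalized ratio in linear scale; because numerator
and denominator are both nFE tracks, the result is invariant to depth
and to the scaling constants.

Confidence bands on aggregate profiles are normal-theory
($\pm 1.96\,\mathrm{SEM}$); the suite checks that the band width agrees
with a bootstrap within 15% on a 50-site panel, which is as much as a
"95% confidence interval" figure legend pins down.

## Contact-map analytics

**Balancing.**  Iterative correction finds weights $w$ with
$w_i c_{ij} w_j$ having equal row sums on unmasked bins (coefficient of
variation below $10^{-8}$ by default, capped at 500 iterations with an
explicit failure, never a silent partial result).  Bins with a raw
marginal under 10% of the median non-zero marginal are masked first.
Iterative correction and Knight-Ruiz balancing converge to the same
doubly-stochastic target; the package implements the former.

**Expected model and arms.**  `expectedCis()` averages balanced contacts
per bin distance, optionally per chromosome arm.  One resolution was
forced by geometry: a centromere-anchored loop has, by definition, one
anchor on the arm boundary, and an insulation window centered on the
centromere always straddles both arms.  A strictly per-arm machinery can
therefore never score the centromere or test centromere-spanning pixels.
The package consequently runs the loop caller, insulation scores, the
report-level APA and centromere-site pile-ups chromosome-wide (this is
also how the standard TAD and loop callers treat chromosomes), while
per-arm expected profiles remain available and are verified to separate
arm-specific decay exponents exactly.

**Decay curves.**  $P(s)$ is the mean contact at bin distance $s$ pooled
over maps, aggregated into geometric bins (ratio 1.15), with the slope
taken by central differences of $\log P$ against $\log s$;
`decaySlope()` fits a weighted least-squares line over a stated range.
On simulated power-law maps the recovered slope is within $\pm 0.05$ of
the true exponent for distances of 5–100 kb at the depths used in the
suite.

**Insulation.**  The score of a bin is $\log_2$ of the summed balanced
contacts in the $w \times w$ square crossing it, relative to the mean of
that sum over the chromosome; it is exactly zero on a uniform map and
invariant to global scaling.  Boundaries are local minima (leftmost bin
of a plateau) whose drop below the surrounding mean exceeds `delta`
(default 0.01), filtered by a rank-based Benjamini-Hochberg q-value
(default threshold 0.01).  This approximates the multi-scale z-statistic
machinery of the reference TAD finder with the two stated windows (5 and
10 kb) and a min-over-windows combination; it is documented as an
approximation, not a reimplementation.

**Loop calling.**  The caller is a simplified donut-background detector:
for every pixel in the tested band (anchor separation > 5 kb), four
local expectations are formed from the donut, lower-left, horizontal and
vertical neighborhoods (outer radius 16 px, inner exclusion 8 px, each
rescaled by the expected profile), the raw count is tested against each
with a Poisson upper tail, and the four p-value sets are BH-adjusted
jointly across all tested pixels at FDR 0.1.  Significant pixels within
2,500 bp (Euclidean) merge by single linkage into one loop at the
cluster centroid.  Single-pixel clusters are kept only below a stricter
q (`fdr/10`), following the established practice of distrusting
unclustered enriched pixels — on structured maps, boundary-adjacent
singletons at $q \approx 0.1$ are the dominant false-positive mode,
while genuine dots always produce multi-pixel clusters.  Lambda-chunking
and the exact post-processing thresholds of the reference implementation
are intentionally not reproduced.

**APA.**  Pile-ups average observed/expected submatrices in ±10-kb
windows around locus pairs separated by more than 5 kb (strictly), with
windows leaving the chromosome skipped and counted; the central score is
the mean of the central 3×3 pixels.  Pile-ups are expected-normalized
only; the four local filters belong to the loop caller.

## The synthetic-data generator

ChIP reads are multinomial over target-genome bins plus one abstract
spike-in compartment; contacts are Poisson around
$\lambda(i,j) = C\,|i-j|^{-\alpha}$ times domain, loop-dot and
centromere-attenuation factors, with $C$ set to match the configured
depth.  These are the simplest noise models consistent with count data.
The spike-in genome is a single uniformly covered compartment because
only its total read counts enter OR/NF.  Fixed seeds give bit-identical
outputs, and every injected feature is exported as a ground-truth table.

Dot shapes: the default dot is a 2-D Gaussian truncated at $3\sigma$.  A
second, `plateau`, shape multiplies exactly the pixels within the
configured radius by the enrichment.  The plateau shape exists because
of a fixture-scale effect: a Gaussian wide enough for the central 3×3
window to read its plateau ($\sigma \ge 4$ bins) carries tail mass
proportional to $\sigma^2$, and on a desk-scale map 40 such dots inflate
the per-distance expected by several percent and depress the balancing
weights at their anchors, so the measurable central score saturates
~10% below the injected enrichment no matter the depth.  APA fidelity is
therefore validated with plateau dots (exact enrichment under the 3×3
core, negligible tail mass) at 40 distinct pair distances, so no
distance stratum of the expected model holds more than one dot; Gaussian
dots remain the default everywhere else.

The two scenario presets share a deterministic two-chromosome genome
(400 kb + 300 kb, centromeres at 200 kb and 100 kb, cohesin sites every
20 kb flanked by convergent gene pairs):

* `wt_like` — loops between adjacent cohesin sites (~20 kb), short
  pericentromeric loops (~8–12 kb), centromere-adjacent domains, mild
  centromere insulation (0.6), low Scc2 at arm sites (enrichment 1.5).
* `wpl1_eco1_like` — 14 centromere-anchored loops of 48–112 kb (mean
  ~77 kb), stronger centromere insulation (0.35), no arm domains,
  cohesin bound fraction reduced to 70% of wild type, and arm-site Scc2
  enrichment raised so that the expected Scc2/Scc1 ratio fold versus the
  wild-type-like preset is exactly 2.53 — the closed form
  $\mathrm{fold} = (\mathrm{bf}^{Scc1}_{wt}/\mathrm{bf}^{Scc1}_{mut})
  \times (e^{Scc2}_{mut}/e^{Scc2}_{wt})$
  follows from the nFE construction because the per-sample effective
  genome sizes cancel between track scaling and NF.  Arm-site Scc2
  enrichment is uniform across sites in each preset, which keeps the
  injected fold exact; the preset therefore does not emulate the
  distance-dependent gradient of Scc2 along arms.

Anchor genes (the centromere-distal, centromere-facing flank of each
wired anchor site) are made longer (3 kb vs 1.2 kb) and more
transcribed, so the gene-context comparisons have a planted effect; the
wild-type-like arm sites are not wired, so the same comparisons are
expected non-significant there.

What passing on these data shows: the formulas, filters, estimators and
callers implement their definitions correctly, recover planted
parameters at realistic depths, and control false positives under the
null.  What it does not show: robustness to the things real sequencing
adds — mappability artifacts, copy-number variation, fragment-length
effects, trans contacts, replicate variation beyond the modeled
multinomial/Poisson noise — nor that the scenario effect sizes are the
biologically true ones.

## Numerical and convention choices

* Coordinates are GRanges-native (1-based closed) in memory; BED,
  bedGraph and BEDPE are 0-based half-open on disk and converted at the
  boundary; GFF3 is read natively.  Out-of-bounds intervals are errors,
  never clipped.
* A position $p$ belongs to bin $\lfloor p/\text{binSize}\rfloor + 1$;
  intervals are quantified over every bin they overlap; distance bins
  and all interval logic are left-closed right-open; the 5-kb centromere
  exclusion is strictly-less-than, so a site at exactly 5 kb is kept.
* Centromeres are stored as midpoints of their annotated intervals, and
  site-to-centromere distance is measured summit-to-midpoint (the
  measurement origin is not pinned down by the published analyses;
  midpoint is the configurable default).
* Summits, quartile ties and heatmap sorts all break ties
  deterministically (leftmost / by coordinate / stable sort).
* The pipeline matches called loop anchors to cohesin sites with a
  tolerance of one matrix bin (1 kb at the scenario resolution), since a
  called anchor is a bin-width interval and the cluster centroid can
  jitter within the dot; the function default remains exact
  intersection.
* Depth normalization offers seeded binomial thinning (default) and
  exact multiplicative scaling.

## Problem sizes

Validation runs on deliberately small instances chosen to give the
estimators comfortable signal: calibration recovery at depth $10^6$ on a
100-kb genome (100 replicates per ratio in the test suite, 50 in the
acceptance script), 1-Mb peak panels with 50 planted sites, 400-bin
decay and loop-caller maps at depths $5\text{–}6\times10^6$, a 1,000-bin
APA map at depth $10^7$, eight 200-kb chromosomes for the centromere
insulation profile, and the two-chromosome scenario genome at
$12.5\times$ coverage per contact map.

## Known limitations

* The loop caller is an operating-characteristics equivalent of the
  reference donut caller, not a bit-compatible reimplementation.
* Insulation boundary significance is rank-based, a deliberate
  simplification of the reference multi-scale statistics.
* Trans contacts, compartments and stripe calling are out of scope;
  pile-ups over user-supplied anchors cover stripe inspection.
* Exact Knight-Ruiz balancing and the `.hic` binary format are not
  implemented; iterative correction and COO text (plus bedGraph/BEDPE)
  are the contracts.
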
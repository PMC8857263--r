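---
title: "Copy-number profiling and analytics for liquid-biopsy CTCs and cfDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number profiling and analytics for liquid-biopsy CTCs and cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidbiopsy)
```

## The problem this package addresses

A liquid biopsy samples a tumor through peripheral blood: circulating
tumor cells (CTCs) give single-cell resolution on the cellular
compartment, and cell-free DNA (cfDNA) gives a bulk readout of the
acellular compartment. Low-pass whole-genome sequencing of either analyte
is summarized as read counts over a fixed partition of the genome into
bins (5000 bins by default here), and per-bin counts approximate local
copy number. From that starting point this package provides the full
downstream analysis chain:

1. **Normalization and segmentation** of bin counts into a genome-wide
   copy-number-alteration (CNA) profile;
2. a **genomic instability (GI) score** summarizing how far a profile
   departs from copy-neutral;
3. **gain/loss calls** at fixed copy-ratio limits and **clone
   detection** from alterations shared between cells;
4. **tumor-fraction estimation** for cfDNA, using a clonal CTC profile
   from the same draw as the reference;
5. **cellular analytics**: CTCs/ml enumeration, kinetics labels,
   SDOM morphometry, and longitudinal variant (VAF) trajectories.

Everything upstream of bin counts — alignment, duplicate removal,
whole-genome amplification, staining and scanning — is out of scope; the
pipeline starts at a `chrom/start/end/count` table. A synthetic-data
module generates every input the pipeline consumes, so the whole chain
is testable without sequencing data.

## Normalization and segmentation

`normalize_counts()` divides each bin count by the sample median over
non-zero bins, producing a copy-ratio profile centered at 1 that is
invariant to sequencing depth. Median rather than mean normalization was
chosen because the median is unaffected by the altered minority of bins
in typical tumor profiles; bins with zero counts are floored at 1e-6
before any logarithm.

`segment_profile()` is a circular-binary-segmentation (CBS) scheme.
Within each chromosome it finds the arc of bins maximizing the pooled
two-sample t-statistic on log2 ratios against the rest of the
chromosome, accepts the split when its permutation p-value falls below
`alpha`, and recurses into the accepted pieces. Defaults are
conventional CBS-style settings: `alpha = 0.01`, `n_perm = 1000`,
`min_width = 5` bins. Two numerical details matter:

* **Tie-breaking and canonical splits.** Ties in the max-t location go
  to the leftmost arc, and an arc ending at the chromosome end is
  rewritten as its equivalent prefix arc, so every split has one
  canonical representation and the search is reproducible bin-for-bin
  against an exhaustive oracle.
* **Permutation shortcuts.** The permutation loop stops as soon as the
  exceedance count guarantees non-significance, and a split whose
  observed statistic exceeds `t_accept = 10` is accepted without
  permutations — the null maximum over all arcs concentrates near
  `sqrt(2 log n_pairs)` (about 5 at chromosome scale), so the decision
  is unchanged while deep recursions on strongly altered chromosomes
  stay fast.

An **undo rule** then re-merges adjacent segments whose log2 means
differ by less than `undo_sd = 1` bin-level noise SD (estimated as
`mad(diff(log2 ratio))/sqrt(2)` over the sample). This suppresses the
occasional spurious split that survives the permutation test on a
5000-bin genome; a one-copy event (log2 difference ~0.58-1 against a
noise SD of ~0.5 at default depth) is far above the merge threshold.
Segment means are reported on the ratio scale as arithmetic means of
member bins, so segmentation preserves each chromosome's mean ratio
exactly. Segments never cross chromosome boundaries; chromosomes shorter
than `2 * min_width` come back as single segments.

## The GI score

For segmented per-bin values re-expressed as the ratio to their median
(RM, so the analyzed vector has median exactly 1), the score is

$$\mathrm{GI} = \sum_{\text{bins}}\left[\tanh\!\big(3\,\lvert\log \mathrm{RM}_i\rvert - 2\big) + \tanh 2\right].$$

Each bin contributes 0 at RM = 1, rises with distance from neutral, and
saturates at $1 + \tanh 2 \approx 1.964$, so a few extreme bins cannot
dominate the genome-wide picture and the score is bounded by
$n_{\text{bins}}(1+\tanh 2)$. Because the argument is $\lvert\log\rvert$,
a complete gain (RM = 2) and a complete loss (RM = 1/2) contribute
identically. Interpretive bands: a copy-neutral profile scores **≤ 30**
(inclusive), a cell with a few chromosomal breaks typically scores
**> 100** (exclusive); between is reported as intermediate.

Two choices here were genuinely open:

* **Log base.** The natural log is used. The gain/loss symmetry holds in
  any base; changing base only rescales what the constants 3 and 2 mean
  in RM units, and with the natural log the per-bin contribution crosses
  half-saturation near a one-copy event, which is what the bands above
  imply.
* **Segmented, not raw, values.** The score is computed on segmented
  per-bin values with RM recomputed from them. On raw ratios at
  realistic single-cell noise, a copy-neutral 5000-bin profile would
  score in the hundreds; only after segmentation suppresses bin noise is
  the ≤ 30 neutral band attainable. The package's simulation study
  (`run_simulation_study()`) verifies both bands under the default noise
  model.

`call_alterations()` applies the heatmap limits: a segment is a gain at
mean ratio ≥ 1.25 and a loss at ≤ 0.75, both inclusive; neutral segments
are not listed.

## Clones and heatmaps

Clonality is defined as **two or more cells sharing two or more genomic
alterations**. The definition leaves the matching rule open, so it is
operationalized as the standard CNV-matching convention: two calls match
when they have the same direction and reciprocal bin overlap ≥ 50%
(configurable), each call matching at most once (greedy by overlap, ties
leftmost). Cells become nodes of a graph with an edge at ≥ 2 shared
alterations; clones are connected components with ≥ 2 members — the
pairwise definition is extended by transitive closure, and alterations
are counted per segment rather than per arm. `cluster_profiles()`
reproduces the display convention: Ward ("ward.D") linkage on Euclidean
distances between per-bin log2 values, columns ordered by the dendrogram
(inputs pre-sorted by sample id so ties are lexicographic), values coded
neutral/gain/loss for the white/red/blue raster that
`heatmap_export()` writes.

## cfDNA tumor fraction from a CTC reference

The read depth behind an alteration in cfDNA is proportional to the
depth over the same region in the tumor profile, so if a clone
contributes a fraction $f$ of the cfDNA, a reference segment with copy
ratio $r$ appears in cfDNA at $(1-f) + f\,r$. The estimator inverts
this per informative segment,

$$f_s = \frac{r_{\mathrm{cf}}(s) - 1}{r_{\mathrm{ref}}(s) - 1},$$

and combines segments with the **median**, clamped to $[0,1]$
(unclamped per-segment values are kept for diagnostics). Informative
segments are those with $\lvert r_{\mathrm{ref}} - 1\rvert \ge 0.25$,
aligning informativeness with the 1.25/0.75 call limits; adding neutral
reference segments provably cannot change the estimate. The median was
chosen over the mean for robustness to a single aberrant segment. A
percentile bootstrap over segments supplies the interval, and estimates
below the 5% confidence floor are flagged, not suppressed. Where several
CTCs form the reference clone, one consensus profile (e.g. the per-clone
median) is supplied — the estimator takes a single reference, and
multi-clone joint deconvolution is out of scope. The companion
1-Mbp-bin HMM approach used in the field for the same quantity (10%
floor) is intentionally not re-implemented.

## Cellular analytics

* **Enumeration.** Analyzed volume = nucleated cells detected on the
  slide / measured WBC concentration. Every CTC-class cell counts
  individually, including each member of a cluster. Positivity is
  ≥ 1 CTC/ml, inclusive.
* **Kinetics.** Between consecutive draws, a change smaller than
  5 CTCs/ml in absolute value (exclusive, per the "< 5" wording) is
  stable; otherwise increasing or decreasing by sign.
* **SDOM.** The quantity is named but not given a formula in the
  field's descriptions; it is formalized here as a signed z-score: the
  cell's channel intensity minus the mean of the 50 nearest WBCs (frame
  Euclidean distance, ties by cell id), divided by their SD. Slides
  with fewer than 50 WBCs use all of them and flag the record. A
  zero-variance background is an explicit error, not a silent Inf. The
  z-score form makes SDOM invariant under affine rescaling of a channel
  (microscope gain/offset).
* **Variant trajectories.** Per-draw VAF tables are merged by
  gene + protein change. "Absent" means *not reported by the assay* —
  never VAF 0 (draws without assay results are skipped entirely).
  Status uses presence at the first and last analyzed draws:
  present/present = persistent, absent/present = acquired,
  present/absent = lost, interior-only = transient; a single draw makes
  everything persistent by convention.

## What the synthetic data does and does not emulate

The generator produces: abstract binned genomes (`make_genome`;
chromosome sizes drawn once per seed to sum exactly to `n_bins`),
event-list clones (`simulate_clone`; explicit intervals and ratios,
later events overwriting earlier — reproducibility was preferred over
stochastic karyotypes), negative-binomial counts (`simulate_cell_counts`,
`simulate_cfdna_counts`), slide feature tables (`simulate_slide`), and
templated longitudinal draw series (`simulate_draw_series`). Bin
coordinates are 0-based half-open in bin units throughout; real-genome
coordinates are cosmetic labels the math never uses.

The noise model is negative-binomial with mean `depth × true ratio`:
dispersion 10 for single cells (whole-genome amplification makes them
noisy) and 50 for cfDNA (cleaner), at depths of 50 and 100 expected
reads per neutral bin respectively. No published per-bin depth or
dispersion was available for these analytes, so the defaults are
conventions chosen to be realistically hard (single-cell coefficient of
variation ~0.35), stated here once and exposed in `lb_config()`.

What is *not* emulated — and therefore what passing tests do not
demonstrate about real data: GC and mappability bias along the genome,
amplification dropout with spatial correlation, subclonal mosaicism
within one cell's reads, segmentation-confounding wave artifacts, real
breakpoint distributions, and imaging artifacts behind the slide
feature tables. The simulations establish that the algorithms are
correct and well-calibrated under their stated model, not that the
model captures every failure mode of the assays.

## Problem sizes and calibration

The package's own calibration study runs at the study scale: 5000-bin,
22-chromosome genomes; 20 replicate seeds per condition; arm-scale
events of at least 200 bins at single-copy ratios 0.5/1.5; cfDNA
mixtures on a 0-10% fraction grid with 20 replicates per point. Under
those conditions the neutral GI band (≤ 30), the aberrant band (> 100),
median fraction recovery within ±0.05 at f ∈ {0.1, 0.3, 0.63}, and a
detection floor at or below 5% are all verified by the test suite and
recomputed end-to-end by `scripts/acceptance.R`.

```{r study, eval = FALSE}
res <- run_simulation_study(lb_config(seed = 1), n_seeds = 20)
aggregate(pass ~ experiment, res, mean)
```

## Known limitations

* Segmentation assumes exchangeable within-segment noise; heavy spatial
  autocorrelation (waves) will fragment segments.
* The fraction estimator assumes one dominant clone shared between the
  CTC reference and the cfDNA; divergent cfDNA subclones bias it
  downward and show up as dispersed per-segment values.
* GI bands were calibrated for ~5000-bin profiles; very different bin
  counts change the meaning of the thresholds 30 and 100.
* The clone rule counts segments, not biological events: a single event
  split by a noisy boundary can count twice toward the ≥ 2 threshold.
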
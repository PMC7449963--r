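---
title: "Methods: bias-corrected footprinting, binding detection and downstream inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bias-corrected footprinting, binding detection and downstream inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footprintr)
```

This vignette documents the models and the design decisions behind
footprintr: what each stage assumes, which parameters matter and why their
defaults are what they are, how the synthetic-data generator relates to
real ATAC-seq, and where the methods' limits are.

## Cutsite signal

Each ATAC-seq fragment marks two Tn5 insertions. Tn5 inserts as a dimer and
duplicates 9 bp, so fragment ends must be shifted towards the interior to
land on the insertion centers: `fragments_to_cutsites()` shifts the start
by +4 and the last base by −5 (the standard convention; both shifts are
arguments). After shifting, the two events of a fragment mark insertion
centers; all downstream windows are anchored on these single-base events.
Events are piled into per-base tracks over the disjoint union of
accessible regions (`merge_intervals()` + `pileup()`); all interval
arithmetic is 0-based half-open.

A consequence of centering both fragment-end events on the insertion point
is that strand no longer distinguishes two different genomic contexts:
both events of an insertion see the same window. The bias estimator
therefore reads all windows on the forward strand by default
(`stranded = FALSE`); scoring minus-strand events on reverse-complement
windows is supported but would split one insertion's evidence across two
mirrored matrices.

## Tn5 bias model

The sequence preference is a dinucleotide weight matrix over a `window`
of 20 bp centered on the insertion point (10 left, 10 right): for each of
the 19 offsets, a probability over the 16 ordered dinucleotides, estimated
from all event-centered windows, with the background taken from windows
centered at every position of the accessible regions (subsampled to
`bg_sample = 100000` positions, seeded). Conditioning the background on
accessible sequence rather than the whole genome keeps the correction from
absorbing open-chromatin base composition. A pseudocount of 1 per cell
keeps all probabilities positive.

Two subtleties drive the estimator design:

* **Overlap leakage.** Dinucleotides at neighboring offsets share a base,
  so the raw marginal frequency at one offset absorbs part of the
  preference acting next door. `estimate_bias(refine = TRUE)` therefore
  refines the marginal estimate by coordinate-wise iterative proportional
  fitting — the maximum-likelihood fit of the product-over-offsets model
  over the background window population — matching one offset's marginal
  at a time with incremental weight updates until the largest log-weight
  update falls below `tol = 1e-3` (at most `max_iter = 50` sweeps; in
  practice a handful suffice).
* **Gauge freedom.** A product of overlapping dinucleotide factors is only
  identified up to moves that shift a single-base potential between
  adjacent offsets (and per-offset constants); such moves change every
  cell yet change no window's total weight. The estimator reports the
  canonical minimum-norm representative (projection onto the orthogonal
  complement of that subspace), and the simulator reports its ground-truth
  matrix in the same canonical form, which is what makes cell-wise
  parameter-recovery checks well defined. The projection provably leaves
  the generated data distribution unchanged.

The per-base bias weight is the product over offsets of model-to-background
probability ratios, computed in log space; windows containing N, or running
off the chromosome, get weight 1 (background). The *expected* track
redistributes each region's observed total proportionally to the bias
weight, so conservation (`sum(expected) == sum(observed)` per region) holds
by construction; this per-region normalization — rather than a global one —
is what makes the *corrected* track (`observed − expected`, optionally
sliding-mean smoothed with `smooth_w`, default 1 = off) mean-zero per
region. Corrected tracks are therefore relative: they expose where cuts
are missing or excess relative to the sequence-bias expectation, not
absolute coverage.

## Footprint scores

`score_params()` fixes the geometry: candidate footprint widths 8–20 bp in
steps of 2 (the span of typical TF core footprints), 30 bp flanks (long
enough to stabilize the local rate, short enough to stay inside a peak),
and a floor of 0 applied to the corrected signal before scoring so that
below-expectation flanks cannot masquerade as accessibility.

For a position and width `w`, let `C` be the mean floored signal over the
centered `w`-window and `L`, `R` the flank means. The default score is

> `max over w of max(0, (L+R)/2 − C)`

— the depletion contrast left on the absolute signal scale. The flank
level *is* the local accessibility, so this one number is depletion
weighted by accessibility: the same fractional dip counts for more where
the region is well covered, and an unreadably sparse region scores near 0.
That is the property that separates it from scale-free depletion
statistics such as FOS, which rank a dip in a barely covered region as
high as one supported by hundreds of cuts.

An additive variant, `combiner = "depletion_accessibility"`, adds an
explicit accessibility term `max(0, (L+R)/2)` to the contrast. We keep it
because making the accessibility reward explicit is the natural first
formalization of a "depletion + accessibility" score, but it is not the
default: the contrast already carries the accessibility scale, so the
extra term double-counts it and adds the flank's sampling noise a second
time; in the bundled simulation it discriminates bound from unbound sites
no better than FOS. This empirical comparison (and the one below for
aggregation) is run in the test suite.

`fos_score()` implements the classical footprint occupancy score
`min over w of (C+1)/(L+1) + (C+1)/(R+1)`, emitted as `−FOS` so that all
score tracks share the higher-is-more-bound convention. Note the +1
pseudocounts make FOS only approximately scale-free at low coverage.

## Binding detection

**Scanning.** PFMs become log-odds matrices
`log2(((count + 1) / (colsum + 4)) / bg)`; the match threshold solves for
the smallest score whose upper-tail probability under the background is at
most 1e-4, computed by exact dynamic-programming convolution of the score
distribution on a 0.001-bit grid. Rounding a column to the grid moves a
k-mer's total by at most half a grid step per column, so the threshold is
lifted by that margin — the reported p-value bound is conservative, exact
to the grid. For motifs shorter than 7 bp no such threshold exists (the
single best k-mer is already more frequent than 1e-4 under a uniform
background); the threshold then falls back to exact-best matches.
Overlapping same-motif, same-strand matches are resolved greedily by score
(ties to the leftmost).

**Per-site scores.** A site's score is the mean of the footprint-score
track over the site extended by half the motif length on each side
(`agg = "mean"`). The window maximum is available (`agg = "max"`) and is
the more natural reading of "the best footprint at this site", but on
sparse signal a maximum chases noise peaks; in the bundled simulation mean
aggregation discriminates bound from unbound sites better for every score
variant, which is why it is the default.

**Normalization.** Condition score columns are full-quantile normalized
over the union of all motifs' sites (limma's implementation, ties
averaged). This implements "normalize towards global TF activity": global
differences in depth or signal-to-noise cannot masquerade as TF changes,
and per-motif differential scores become comparable across a volcano.
The flip side is that quantile normalization is zero-sum — if *every*
motif truly shifts in one direction, the shift is removed; and on very
small motif panels one strong TF visibly mirrors into the others (see the
README example with two motifs).

**Bound/unbound.** Per motif and condition, a two-component Gaussian
mixture is fit to `log(1 + score)` (mclust, unequal variances, with a
two-means fallback for inputs mclust cannot handle); the threshold is the
smallest score whose posterior probability of the higher-mean component
reaches 0.5, evaluated on a 1024-point grid between the component means.
Degenerate fits — component means within 1e-3, a component weight below
0.01, no posterior crossing, or fewer than `min_sites = 50` sites — declare
all sites unbound, which is the conservative failure mode. The log1p
transform stabilizes the heavy right tail of footprint scores.

**Differential binding.** Per motif, the raw score is the difference of
mean normalized site scores between conditions. Whether that difference is
large *for a site set of this size* is judged against a background of 100
random subsamples of the same size drawn from the union of all sites
(seeded); the standardized score is a z-value with a two-sided normal
p-value. Known limitation: a motif with a very strong true shift
contaminates the shared background pool, biasing the other motifs' z
slightly negative; the effect shrinks with panel size (1/n_motifs) and is
why calibration properties are stated over seeds and realistic panel
sizes. Per-site changes use `log2((s2 + 1)/(s1 + 1))`, the +1 stabilizing
near-zero scores.

## Aggregate metrics

`aggregate_footprints()` averages signal in ±60 bp windows around sites
(minus-strand windows reversed); sites whose window leaves the scored
region are dropped. The footprint depth is the mean over two 20 bp flank
windows immediately outside the motif minus the mean over the motif
window. By default it is divided by the flank mean (relative depth, so
TFs of different accessibility are comparable; 1 = complete depletion,
negative = anti-footprint). On corrected signal the flank mean is ~0 by
construction and the ratio is meaningless, so `relative = FALSE` reports
the absolute difference in per-base cut units — comparable across the
observed, expected and corrected tracks of one dataset, which is what
before/after-correction comparisons need.

`measurable_footprint_test()` compares the observed FPD against aggregates
built at the same number of positions drawn uniformly within the scored
regions (so the null preserves accessible-sequence composition, seeded,
`n_null >= 100`); a footprint is measurable when the observed FPD exceeds
the null's 95th percentile.

## Motif clustering

TF similarity is the overlap coefficient of binding-site sets: the
fraction of the *smaller* set overlapping the other (>= `min_bp` = 1 bp).
The min-set denominator makes a motif nested inside a larger motif's site
set score 1 — appropriate for TF families sharing near-identical motifs,
and it keeps the measure symmetric. Distance is 1 − overlap, so a tree
height of 0.2 means 80% site overlap. Trees use complete linkage
(guaranteeing monotone merge heights, so "cut at 0.5" cleanly means "more
than half their sites shared"), with leaves ordered lexicographically
before clustering so ties break deterministically; flat clusters are cut
at 0.5 by default and trees serialize to newick via ape.

## TF network

Sites are assigned to every gene whose promoter window overlaps them by
>= 1 bp; the window is −10000/+1000 around the TSS, strand-aware, and
multi-gene assignments are kept. An edge A→B requires a site of motif A in
the promoter of a gene encoding motif B with `log2fc > 0` *and* bound in
the target condition (`require_bound`); requiring the bound state keeps
edges supported by actual binding rather than fold-change noise, and a
flag disables it. Levels are breadth-first distances from the source
motif; nodes beyond `max_level = 2` (three layers) are pruned; self-edges
are kept in the edge list but never affect levels.

## The simulator

`sim_config()` / `simulate_dataset()` generate: an i.i.d. uniform genome
(200 kb over 2 chromosomes); 200 non-overlapping peaks (widths ~N(400, 50)
bp, floored at 200) with Gamma-distributed accessibility multipliers
(mean 1, CV 0.7 — peak heights in real data span an order of magnitude);
motif consensus instances implanted at known positions (150 per motif,
kept >= 70 bp inside peak edges so aggregate windows fit); a random true
DWM with cell log-weights ~N(0, 0.15·`bias_strength`), giving per-base
weights spanning roughly e^±1.3 at strength 1; and per-condition bound
labels with exact per-motif counts, drawn preferentially in more
accessible peaks (TF binding both requires and maintains accessibility).
Insertions are Poisson per peak (mean `reads_per_peak = 200` ×
accessibility, about one cut event per bp — mid-depth ATAC) with per-base
probabilities proportional to accessibility × bias weight ×
(1 − `footprint_depth`·bound), and each insertion at p is emitted as the
fragment [p−4, p+6) so the standard shifts place both cut events back at
p. The default `footprint_depth` of 0.5 reflects a mid-residence-time TF
that halves the local cut rate. An optional anti-Tn5 motif subtracts
`anti_strength = 0.3` from its dinucleotides' log-weights — a
sequence-driven false footprint with no binding, the control for
correction.

What the simulator does *not* emulate: fragment-length mixtures and
nucleosome phasing, replicate and batch noise, non-uniform genomic base
composition, soft (mismatched) motif instances, and footprint shapes wider
than the motif. Passing tests therefore demonstrate correctness of the
machinery and its behavior under controlled bias/footprint/accessibility
structure, not performance on real chromatin.

## Problem sizes and numerical choices

The bundled analyses run on desk-scale data by design: 200 kb genomes,
~200 peaks, 10^4–10^5 events, motif panels of 2–100, mixture fits on
~2000 sites, 100 background subsamples, 100–200 null aggregates, 20-seed
power batches. Determinism is contracted everywhere randomness enters
(background subsampling, differential subsamples, null aggregates,
simulation) via explicit seeds; the same seed gives bit-identical output,
and seeded helpers restore the caller's RNG state. Score discretization
for motif thresholds is 0.001 bits; mixture degeneracy bounds are 1e-3
(means) and 0.01 (weight); conservation tolerances are 1e-6 relative per
region. bedGraph is the interchange format for all tracks (runs of equal
value merged, exact round-trip).

## Known limitations

* Corrected tracks are mean-zero per region; any statistic dividing by
  their local level (relative FPD, strict FOS) needs the absolute or
  floored variants discussed above.
* The differential background test is mildly anti-conservative in the
  presence of a very strong single-TF shift (background contamination),
  and quantile normalization removes truly global activity shifts.
* The DWM is identifiable only up to gauge; cell-wise comparisons between
  independently estimated matrices are meaningful only in the canonical
  parametrization both this estimator and the simulator report.
* On sparse signal the advantage of accessibility-aware scoring over FOS
  is real but modest, because FOS's +1 pseudocounts leak accessibility at
  low coverage; the gap widens with depth.
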
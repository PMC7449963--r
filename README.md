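# footprintr

Digital genomic footprinting for ATAC-seq in R: Tn5 sequence-bias
correction, continuous footprint scoring, bound/unbound classification of
transcription-factor (TF) binding sites, differential TF binding between
conditions, aggregate footprint metrics, motif clustering by binding-site
overlap, and TF-to-TF network inference — with a seeded synthetic-data
simulator that provides ground truth for every step.

## The problem

ATAC-seq reports chromatin accessibility at base-pair resolution: each
sequenced fragment marks two Tn5 transposase insertions. A DNA-bound protein
shields its footprint from Tn5, so a TF binding site inside an accessible
region shows up as a local dip ("footprint") in the per-base cutsite signal.
Two things make naive footprint calling unreliable:

1. **Tn5 sequence preference.** Tn5 inserts preferentially into certain
   sequence contexts. Motifs whose sequence disfavors Tn5 look like
   footprints even when nothing is bound (false positives); motifs whose
   sequence attracts Tn5 can hide real footprints (false negatives).
2. **Sparsity.** At realistic depths, a 10 bp window holds a handful of
   cuts; a pure depletion statistic cannot tell "no footprint" from "no
   reads".

## The model

**Bias correction.** Tn5 preference is modelled as a dinucleotide weight
matrix (DWM): for a 20 bp window centered on the insertion point, the
probability of each of the 16 ordered dinucleotides at each of the 19
window offsets, estimated from observed cutsites and contrasted against the
dinucleotide composition of the accessible regions. Because adjacent
offsets share a base, marginal counts mix neighboring preferences; the
estimator refines them by coordinate-wise iterative proportional fitting
(the maximum-likelihood fit of the product-over-offsets model) and reports
the canonical minimum-norm parametrization. The per-base bias weight

&nbsp;&nbsp;&nbsp;&nbsp;w(p) = prod over offsets r of P_dwm(d_r(p)) / P_bg(d_r(p))

redistributes each region's observed cut total into an *expected* track;
*corrected = observed − expected* removes the sequence-driven structure
(per region the corrected values sum to 0).

**Footprint score.** For each position and candidate footprint width `w`
(8–20 bp), with `C` the mean floored corrected signal over the center
window and `L`, `R` the means over 30 bp flanks, the score is
`max over w of max(0, (L+R)/2 − C)` — the depletion contrast left on the
absolute signal scale, so the same fractional dip scores higher where the
region is more accessible. The classical footprint occupancy score
`FOS = min over w of (C+1)/(L+1) + (C+1)/(R+1)` is provided (sign-flipped)
as the pure-depletion baseline.

**BINDetect.** Motifs (JASPAR PFMs) are scanned on both strands with an
exact dynamic-programming score threshold at match p = 1e-4; per-site
scores are quantile-normalized across conditions, classified bound/unbound
per motif with a two-component Gaussian mixture on log(1+score), and
summarized per motif as a differential binding score standardized against
subsampled background site sets (the volcano table), plus per-site
`log2((s2+1)/(s1+1))` fold changes.

**Downstream.** Aggregate profiles and the footprint-depth (FPD) metric
with randomized-null "measurable footprint" calls; motif trees from the
overlap coefficient of binding-site sets (tree distance 0.2 = 80% site
overlap, flat clusters cut at 0.5); and a directed TF→TF network from
binding sites with log2FC > 0 in promoter windows (−10000/+1000 around the
TSS, strand-aware), layered by breadth-first level from a source TF.

## Worked example

Simulate a two-condition dataset in which motif `simB` gains binding
(bound fraction 0.2 → 0.6) while `simA` stays at 0.3, then run the full
chain:

```r
library(footprintr)

bf  <- matrix(c(0.3, 0.3, 0.2, 0.6), nrow = 2, byrow = TRUE)
sim <- simulate_dataset(sim_config(seed = 1, bound_fraction = bf))

sizes   <- nchar(sim$genome)
bundles <- lapply(sim$fragments, function(fr)
  bias_correct(fragments_to_cutsites(fr, chrom_sizes = sizes),
               sim$genome, sim$peaks, seed = 1))
scores  <- lapply(bundles, function(b) footprint_score(b$corrected))

motifs <- motif_models(consensus_pfms(default_sim_motifs()))
sites  <- scan_motifs(motifs, sim$genome, merge_intervals(sim$peaks)) |>
  score_sites(scores) |>
  normalize_scores() |>
  classify_bound() |>
  site_log2fc("A", "B")

differential_binding(sites, "A", "B", seed = 1)
#> # A tibble: 2 × 8
#>   motif_id n_sites mean_A mean_B diff_raw differential_score p_value neg_log10_p
#> 1 simA         159  0.259  0.227  -0.0320              -3.03 0.00244        2.61
#> 2 simB         157  0.217  0.250   0.0324               3.03 0.00241        2.62
```

`simB` is called up in condition B (z = +3.0, p = 0.0024). With only two
motifs, quantile normalization is zero-sum, so `simA` mirrors `simB`
downward — on realistic motif panels (hundreds of motifs) a single TF's
change barely moves the background. Checking predictions against the
simulator's truth:

```r
truth_metrics(sites, sim$truth, "B")
#> # A tibble: 1 × 5
#>   n_matched auroc precision recall bound_fraction_error
#> 1       300 0.800 0.720     0.496  0.14

prof <- aggregate_footprints(dplyr::filter(sites, motif_id == "simB", bound_B),
                             bundles$B$corrected)
fpd(prof, relative = FALSE)
#> [1] 0.807
autoplot(prof)   # aggregate footprint plot, motif edges dashed
```

The bound-site aggregate shows a 0.8 cuts/bp deep footprint on the
corrected signal. A shell front end wrapping the same functions lives at
`inst/cli/fpk.R` (`fpk simulate`, `fpk run --config run.json`, plus one
subcommand per stage).

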
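---
title: "Cross-tissue temporal coordination: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue temporal coordination: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circasync)
options(circasync.verbose = FALSE)
```

## The problem

Circadian transcriptomic studies usually ask whether individual genes are
rhythmic within one tissue. `circasync` asks a different question: how
tightly are temporal expression profiles *aligned* — between genes within a
tissue, between tissues, and for a single gene across the whole body — and
how does that alignment change between experimental conditions such as ad
libitum (ALF) versus time-restricted feeding (TRF)? The motivating setting
is a multi-tissue design (on the order of 22 tissues sampled every 2 h over
24 h, two replicates per timepoint, two feeding conditions) and a defined
gene program such as the mitochondria-associated transcriptome, but nothing
in the package is specific to those choices.

All coordination metrics are built from the sample Pearson correlation of
two temporal profiles over the within-cycle timepoints. The time grid is
treated as plain sample order — no circular statistics, no rhythm model is
fit — because the quantities of interest are similarities of observed
trajectories, not parametric phase estimates.

## Preprocessing model

The expected inputs are per-tissue gene × timepoint matrices of normalized
expression (the package is agnostic to the upstream normalization; it never
performs library-size or TMM normalization itself). The preparation chain
is fixed in order:

1. **Replicate averaging** (`average_replicates()`): the arithmetic mean of
   biological replicates per timepoint. Averaging precedes every other
   step.
2. **Detection filtering** (`filter_detected()`): a gene is kept when its
   averaged expression exceeds `min_value` at *every* timepoint. "Detected"
   is not a standardized notion; the default `min_value = 0` (strictly
   positive everywhere) is the weakest reading consistent with "detected at
   all sampled timepoints" and is configurable.
3. **Min-max normalization** (`minmax_normalize()`): each gene is mapped to
   `(x - min)/(max - min)` across its own timepoints. This is a per-gene
   positive affine map, so every Pearson correlation — and hence every
   downstream coordination metric — is mathematically unchanged by it; its
   only role is to make waveform plots and cluster means comparable across
   genes. The test suite verifies the invariance numerically to 1e-10.
   Genes with zero temporal variance have no defined correlation and are
   dropped here with a warning. Amplitude analyses deliberately bypass this
   step and use unscaled values.

Gene symbols are matched case-sensitively after whitespace trimming;
duplicate symbols within a tissue are an error at read time.

## Significance of correlations

Pair significance uses the exact two-sided t transform
`t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom, at
unadjusted `alpha = 0.05` by default. No multiple-testing correction is
applied anywhere: significant-pair counts are descriptive summaries of a
correlation distribution, not gene-level hypothesis tests, and correcting
them would only rescale every count by the same monotone rule. Internally,
counting uses the equivalent critical-|r| threshold
(`critical_r(n, alpha)`, 0.576 at n = 12) rather than computing a p-value
per matrix entry; the two formulations are identical because p is strictly
monotone in |r| at fixed n, and this makes the 231-tissue-pair
cross-correlation stage cheap.

## Intra- and inter-tissue summaries

The intra-tissue synchronization strength of a tissue is the mean of |r|
over unordered off-diagonal gene pairs of its correlation matrix. The
diagonal is excluded by default: self-correlations are identically 1 and
would only add a gene-count-dependent offset. A diagonal-inclusive flag
exists for comparability with matrix-wide conventions.

Inter-tissue analysis supports two granularities, both first-class:

- `all_pairs`: the full genes(A) × genes(B) cross-correlation matrix,
  summarized exactly like an intra-tissue matrix (there is no diagonal
  concept). This is the default for tissue-pair strength because
  inter-tissue summaries are computed "in the same manner" as intra-tissue
  ones.
- `same_gene`: the vector r(gene g in A, gene g in B) over shared genes —
  the ingredient of the whole-body score.

The per-tissue summed strength Σ|r| aggregates *pair-level mean* |r| (not
raw entry sums) so tissues with different detected-gene counts remain
comparable. Condition comparisons use an unpaired two-tailed t-test; for a
single tissue the observation unit is the population of off-diagonal |r|
values, a documented choice isolated behind `compare_intra()` (the
underlying pairs share genes, so the test is descriptive rather than an
exact inference).

## Whole-body synchronization score and the clock-like threshold

For gene *g* under one condition the score is the **signed** sum of
same-gene correlations over all unordered tissue pairs. Signs are preserved
deliberately: using |r| would reward anti-phase relationships, whereas the
score is meant to capture in-phase, body-wide alignment. The ceiling is
C(T, 2) = 231 at 22 tissues. By default only genes present (and
non-constant) in every tissue are scored, so all scores share that ceiling;
with `require_all_tissues = FALSE` genes are scored over their available
pairs and `n_pairs_used` is reported so users can filter or rescale — how
to score partially-present genes is genuinely underdetermined, so both
behaviors are exposed rather than guessed.

The "clock-like" threshold is calibrated from a benchmark list of core
circadian genes: sort their scores descending and place the threshold at
the midpoint of the *first pronounced decline*. Two operationalizations are
provided — `largest_gap` (midpoint of the maximal consecutive drop; the
default) and `first_gap` (the first drop exceeding `gap_factor` × the
median gap, falling back to largest-gap) — plus a `manual` mode for an
externally chosen operating value (e.g. a published y = 60). The pass set
is identical whichever point inside the gap is reported; the midpoint is a
symmetric convention. A benchmark list should contain both strongly and
weakly synchronized clock genes: the decline being detected is the boundary
between them.

## Temporal waves

Globally synchronized genes are clustered by complete linkage on
d = 1 − r — the same engine as the heatmap ordering — and the tree is cut
at a fixed height, default 1.0 (the r = 0 boundary: members of one wave
correlate positively). Gene similarity is computed, by default, on
per-tissue min-max profiles concatenated in a fixed (sorted) tissue order,
because averaging tissues first can cancel anti-phase organs; a
`whole_body` mode using the mean waveform is available. Clustering uses
`stats::hclust`; with ties in merge heights `hclust`'s own deterministic
ordering applies — merge heights themselves, which every numerical check in
the test suite compares against a naive O(G³) agglomeration oracle, do not
depend on tie-breaking.

## Pathway-term enrichment

Hierarchical annotations ("Root > Mid > Leaf", possibly several paths per
gene) are expanded so each level of each path is one term occurrence. A
cluster's **term frequency** is its occurrence count; its **term ratio** is
that count divided by the term's occurrences across the whole annotation
universe. Occurrences are counted per path appearance by default (a level
shared by two paths of one gene counts twice, matching the ratio arithmetic
of a per-occurrence universe); a per-gene de-duplicated mode exists. The
broad root "Metabolism" is excluded by default as uninformative; the
exclusion set is configurable and case-sensitive after trimming. Rankings
report the top 5 by frequency and by ratio, ties broken by the other metric
then alphabetically. No enrichment p-values are computed — these are
compositional rankings, not tests.

## Amplitude

Circadian amplitude is the peak-to-trough range (max − min) of the
replicate-averaged waveform in original expression units; no cosinor or
other fit is performed, so the definition is assumption-free and exact on
the sampled grid (a half-range option exists). Ties on extremes resolve to
the earliest timepoint for deterministic peak phases. Condition effects are
expressed as amplitude ratios or log2 ratios per tissue, and the
across-tissue effect is assessed with a one-sample t-test of the per-tissue
log2 ratios against 0 — the log scale makes reciprocal changes symmetric;
raw ratios against 1 remain available.

## The synthetic-data generator

`generate_dataset()` simulates
`x = b + a * cos(2 * pi * (t - phase) / 24) + e`, `e ~ N(0, noise_sd²)`,
per replicate, clipping negatives at zero (the clipped count is logged and
is rare under the defaults, ~0.6% of values), then averages replicates.
Gene classes:

- **aligned** genes share a global phase per gene; each tissue adds
  Gaussian jitter whose SD is the per-condition `phase_dispersion_h`
  (defaults: 6 h for the ALF-like condition, 1.5 h for the TRF-like one),
  and their amplitudes are multiplied by the per-condition `amplitude_gain`
  (1 vs 1.5) — together these encode "restricted feeding tightens and
  amplifies cross-tissue rhythms";
- **scattered** genes draw an independent uniform phase in every tissue
  (expected score ≈ 0);
- **benchmark** genes are appended clock-like controls with small fixed
  jitter (0.5 h in both conditions) and a 1.5× amplitude factor;
- **decoy** genes are appended weak controls (scattered phases, 0.5×
  amplitude) emulating the low-ranked members of a curated clock-gene list
  — without them a benchmark list has no internal decline for threshold
  calibration to find.

Defaults: 22 tissues, 500 genes (10% aligned), timepoints 0–22 h by 2 h,
2 replicates, baseline 50 ± 10, amplitude 20 ± 5, `noise_sd = 10`, 12
benchmarks + 3 decoys. The noise level (half the mean amplitude) was chosen
once as a realistic signal-to-noise for replicate-averaged bulk expression:
strong rhythms remain clearly detectable while correlation attenuation is
material, so condition contrasts in amplitude translate into detectable
intra-tissue |r| differences. `phase_groups_h` optionally plants discrete
phase groups among aligned genes for wave-recovery experiments.

Reproducibility: all draws flow from one config seed. Per-(gene, tissue)
baselines and amplitudes come from a per-tissue substream shared by both
conditions (so conditions are comparable and adding tissues never
reshuffles earlier tissues' draws); phases and noise come from a
per-(condition, tissue) substream.

What the generator does *not* emulate: count noise (no negative-binomial
layer), non-sinusoidal waveforms, tissue-specific baselines correlated with
function, shared regulatory covariance between genes beyond phase
alignment, or missing genes per tissue. Tests passing on this model
therefore certify the *metrics and pipeline*, not biological discovery on
real data.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the recovery study at its full
default scale (22 tissues × 515 genes × 2 conditions) and smaller designs
(4–8 tissues, tens of genes) elsewhere; these sizes were chosen so the
whole suite completes in seconds while Monte-Carlo margins stay wide.
Oracle comparisons use 1e-10–1e-12 tolerances for reals and exact equality
for counts. Correlations are clamped to [−1, 1] after floating-point
rounding; correlation of a constant profile is an error surfaced to the
caller rather than an NA. Stage outputs are plain TSV/JSON written with
fixed conventions so identical seeds give byte-identical runs.

## Known limitations

- Significant-pair counts inherit the descriptive, uncorrected convention;
  they should not be read as FDR-controlled discoveries.
- The t-test comparing two correlation matrices treats |r| values as
  independent observations, which they are not; its p-values are
  heuristic rankings of effect strength.
- Scores of genes absent from some tissues are not rescaled by default;
  cross-gene comparisons mix ceilings unless `require_all_tissues = TRUE`
  (the default) or the user normalizes by `n_pairs_used`.
- The fixed-height wave cut is a visualization convention; cluster counts
  can change under small cut-height changes when between-wave correlations
  sit near the cut.
```{r}
sessionInfo()
```
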
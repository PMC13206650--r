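# circasync

Quantifying how tightly gene expression rhythms are coordinated **within and
across tissues** in multi-tissue circadian time-course experiments — for
example, a design in which many tissues are sampled every 2 h over a 24-h
cycle under two feeding schedules (ad libitum, ALF, vs time-restricted
feeding, TRF) and the question is whether restricted feeding synchronizes a
gene program (such as the mitochondria-associated transcriptome) across the
whole body.

The package is aimed at computational biologists who already have
per-tissue gene × timepoint expression matrices (normalized counts or
equivalent) and want reproducible coordination metrics rather than per-gene
rhythmicity calls.

## The metrics

For temporal profiles sampled at *n* timepoints, all coordination metrics
derive from the sample Pearson correlation *r* between profiles:

- **Intra-tissue synchronization strength** — the mean absolute correlation
  ⟨|r|⟩ over all unordered gene pairs of one tissue's correlation matrix,
  together with the count of pairs significant at unadjusted two-sided
  p < α (equivalently |r| above the critical value
  t<sub>1−α/2,n−2</sub> / √(t² + n − 2); 0.576 at n = 12, α = 0.05).
- **Inter-tissue synchronization** — the same summaries on the
  genes(A) × genes(B) cross-correlation matrix of each tissue pair, plus the
  per-tissue summed strength Σ|r| over its incident pairs and a network edge
  table.
- **Whole-body synchronization score** — per gene *g*,
  S<sub>g</sub> = Σ<sub>(A,B)</sub> r(x<sub>g,A</sub>, x<sub>g,B</sub>) over
  all unordered tissue pairs, **signed** so anti-phase tissues subtract; the
  ceiling is C(T, 2) (231 for 22 tissues). A "clock-like" threshold is
  calibrated as the first pronounced decline in the descending sorted scores
  of a curated benchmark (core circadian) gene list.
- **Temporal waves** — complete-linkage clustering of globally synchronized
  genes on the dissimilarity d = 1 − r, cut at a fixed dendrogram height
  (default 1.0, the r = 0 boundary).
- **Term enrichment** — hierarchical pathway-term frequency (occurrence
  counts within a cluster) and ratio (cluster count / universe count), with
  the broad "Metabolism" root excluded and top-5 rankings by each metric.
- **Amplitude** — peak-to-trough range of replicate-averaged waveforms on
  *unscaled* expression values, with ratio / log2-ratio condition
  comparisons and one-sample t-tests.

Correlation analyses operate on per-gene min-max normalized profiles;
normalization is affine per gene, so every correlation-derived quantity is
provably unchanged by it (and the test suite checks this to 1e-10).
Amplitude analyses always use raw values.

A fully ground-truthed synthetic generator (`sim_config()` /
`generate_dataset()`) emulates the 22-tissue, 12-timepoint, 2-replicate,
two-condition design with per-gene cosine rhythms, per-tissue phase
dispersion that differs by condition, and additive Gaussian noise, so every
stage is testable without external data.

## Worked example

```r
library(circasync)
options(circasync.verbose = FALSE)

cfg <- sim_config(n_tissues = 8, n_genes = 100, seed = 1)
g   <- generate_dataset(cfg)
g$dataset
#> <study_dataset> 2 condition(s) x 8 tissue(s), 16 series
#>   provenance: circasync synthetic study (seed 1)

st_alf <- score_table(g$dataset, "ALF")
st_trf <- score_table(g$dataset, "TRF")
st_trf
#> <sync_score_table> TRF: 115 genes over 8 tissues; score range [-3.30, 26.88]

bm  <- designate_benchmarks(g$truth)
cal <- calibrate_threshold(st_alf$scores[bm$genes], "largest_gap")
cal
#> <threshold_calibration> strategy = largest_gap, threshold = 13.845 (drop between BM11 and DC01)

alf <- global_set(st_alf, cal$threshold)
trf <- global_set(st_trf, cal$threshold)
length(alf); length(trf)
#> [1] 12
#> [1] 22
overlap_sets(alf, trf)[1:3]
#> $n_shared   [1] 12
#> $n_unique_A [1] 0
#> $n_unique_B [1] 10

wave_clusters(trf, g$dataset, "TRF")
#> <wave_clustering> 5 cluster(s) at cut height 1.00 (concatenated profiles)
#> 1 2 3 4 5
#> 6 6 6 2 2
```

Reading: with 8 tissues the score ceiling is C(8,2) = 28; the 12 strong
benchmark genes score near it, the weak decoys score near 0, and the
largest-gap calibration lands between them (13.8). Under the tighter-phase
TRF-like condition 22 genes clear the clock-like threshold versus 12 under
ALF, every ALF gene remaining a TRF gene — the directional pattern these
metrics are designed to expose. The passing TRF genes then split into
temporal waves by peak phase.

An end-to-end run (simulate → prepare → intra → inter → global → pathways →
amplitude) with TSV/JSON outputs and a reproducibility manifest:

```r
run_pipeline("out_dir", sim = sim_config(seed = 1))
```

or from a shell: `Rscript inst/scripts/circasync_run.R --out-dir out --seed 1`.

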
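#' Configuration for the synthetic circadian study generator
#'
#' Defines a multi-tissue, two-condition circadian expression study with
#' per-gene cosine rhythms. Defaults emulate a 22-tissue design sampled every
#' 2 h over 24 h with 2 replicates per timepoint under an ad libitum (ALF)
#' and a time-restricted (TRF) feeding condition: 500 genes of which 10% are
#' cross-tissue phase-aligned, plus 12 appended strong clock-like benchmark
#' genes and 3 deliberately weak decoys for threshold calibration. Tighter
#' per-tissue phase dispersion (1.5 h vs 6 h) and a 1.5x amplitude gain for
#' aligned genes encode the stronger cross-tissue coordination of the TRF
#' condition.
#'
#' @param n_tissues Number of tissues (>= 2; default 22).
#' @param n_genes Number of ordinary genes, split into aligned and scattered
#'   by `aligned_fraction`; benchmark/decoy genes are appended on top.
#' @param timepoints_h Sampling grid within one cycle (default 0, 2, ..., 22).
#' @param n_replicates Biological replicates per timepoint (default 2).
#' @param conditions Condition ids (default `c("ALF", "TRF")`).
#' @param baseline_mean,baseline_sd Per-gene-tissue baseline expression.
#' @param amplitude_mean,amplitude_sd Per-gene-tissue cosine amplitude.
#' @param noise_sd Additive Gaussian noise per replicate measurement.
#' @param phase_dispersion_h Named vector, condition -> SD (hours) of the
#'   per-tissue phase jitter of aligned genes.
#' @param aligned_fraction Fraction of `n_genes` given a shared global phase
#'   across tissues; the rest get independent uniform phases per tissue.
#' @param amplitude_gain Named vector, condition -> multiplicative amplitude
#'   factor applied to aligned genes.
#' @param benchmark_n Number of appended strong benchmark genes (clock-like:
#'   smallest phase dispersion, highest amplitude).
#' @param benchmark_decoys Number of appended weak decoy genes emulating
#'   low-ranked members of a curated clock-gene list.
#' @param benchmark_dispersion_h Phase jitter SD of benchmark genes (both
#'   conditions).
#' @param benchmark_amplitude_factor Amplitude multiplier for benchmarks.
#' @param decoy_amplitude_factor Amplitude multiplier for decoys.
#' @param phase_groups_h Optional vector of global phases; aligned genes are
#'   assigned to these phases round-robin (planted temporal waves) instead of
#'   uniform global phases.
#' @param seed Integer seed; the single source of randomness.
#' @return A validated `"sim_config"` list.
#' @export
sim_config <- function(n_tissues = 22, n_genes = 500,
                       timepoints_h = seq(0, 22, by = 2), n_replicates = 2,
                       conditions = c("ALF", "TRF"),
                       baseline_mean = 50, baseline_sd = 10,
                       amplitude_mean = 20, amplitude_sd = 5,
                       noise_sd = 10,
                       phase_dispersion_h = c(ALF = 6, TRF = 1.5),
                       aligned_fraction = 0.1,
                       amplitude_gain = c(ALF = 1, TRF = 1.5),
                       benchmark_n = 12, benchmark_decoys = 3,
                       benchmark_dispersion_h = 0.5,
                       benchmark_amplitude_factor = 1.5,
                       decoy_amplitude_factor = 0.5,
                       phase_groups_h = NULL, seed = 1) {
  cfg <- list(n_tissues = as.integer(n_tissues), n_genes = as.integer(n_genes),
              timepoints_h = as.numeric(timepoints_h),
              n_replicates = as.integer(n_replicates),
              conditions = as.character(conditions),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
              noise_sd = noise_sd,
              phase_dispersion_h = phase_dispersion_h,
              aligned_fraction = aligned_fraction,
              amplitude_gain = amplitude_gain,
              benchmark_n = as.integer(benchmark_n),
              benchmark_decoys = as.integer(benchmark_decoys),
              benchmark_dispersion_h = benchmark_dispersion_h,
              benchmark_amplitude_factor = benchmark_amplitude_factor,
              decoy_amplitude_factor = decoy_amplitude_factor,
              phase_groups_h = phase_groups_h, seed = as.integer(seed))
  if (cfg$n_tissues < 2) stopf("config error: n_tissues must be >= 2")
  if (cfg$n_genes < 2) stopf("config error: n_genes must be >= 2")
  if (cfg$n_replicates < 1) stopf("config error: n_replicates must be >= 1")
  if (cfg$aligned_fraction < 0 || cfg$aligned_fraction > 1)
    stopf("config error: aligned_fraction must lie in [0, 1]")
  sds <- c(cfg$baseline_sd, cfg$amplitude_sd, cfg$noise_sd,
           cfg$phase_dispersion_h, cfg$benchmark_dispersion_h)
  if (any(sds < 0)) stopf("config error: all sd parameters must be >= 0")
  if (is.null(names(cfg$phase_dispersion_h)) ||
      !all(cfg$conditions %in% names(cfg$phase_dispersion_h)))
    stopf("config error: phase_dispersion_h needs one entry per condition")
  if (is.null(names(cfg$amplitude_gain)) ||
      !all(cfg$conditions %in% names(cfg$amplitude_gain)))
    stopf("config error: amplitude_gain needs one entry per condition")
  if (cfg$benchmark_n < 0 || cfg$benchmark_decoys < 0)
    stopf("config error: benchmark counts must be >= 0")
  structure(cfg, class = "sim_config")
}

tissue_seed <- function(seed, s) (seed * 1009L + 7919L * s) %% 2147483629L
cond_tissue_seed <- function(seed, s, ci)
  (seed * 1013L + 7919L * s + 104729L * ci) %% 2147483629L

#' Generate a synthetic circadian study with known ground truth
#'
#' Simulates `x = b + a * cos(2 * pi * (t - phase) / 24) + noise` per
#' replicate, clips negatives at 0 (clipped count logged), and averages
#' replicates. Aligned and benchmark genes share a global phase per gene with
#' Gaussian per-tissue jitter (SD set per condition for aligned genes, fixed
#' and small for benchmarks); scattered and decoy genes draw independent
#' uniform phases in every tissue. Baselines and amplitudes are drawn once
#' per (gene, tissue) from a per-tissue RNG substream, so both conditions
#' share them and adding tissues does not reshuffle earlier draws.
#'
#' @param config A [sim_config()].
#' @return A list: `dataset` (a replicate-averaged [study_dataset()]),
#'   `truth` (list of `genes` and `per_tissue` data.frames), `n_clipped`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_aligned <- round(config$aligned_fraction * config$n_genes)
  n_scattered <- config$n_genes - n_aligned
  genes <- c(sprintf("G%04d", seq_len(config$n_genes)),
             if (config$benchmark_n) sprintf("BM%02d", seq_len(config$benchmark_n)),
             if (config$benchmark_decoys) sprintf("DC%02d", seq_len(config$benchmark_decoys)))
  label <- c(rep("aligned", n_aligned), rep("scattered", n_scattered),
             rep("benchmark", config$benchmark_n),
             rep("decoy", config$benchmark_decoys))
  n_total <- length(genes)
  tissues <- sprintf("T%02d", seq_len(config$n_tissues))
  tp <- config$timepoints_h
  nt <- length(tp); nr <- config$n_replicates
  coherent <- label %in% c("aligned", "benchmark")

  phase_global <- with_seed(config$seed, stats::runif(n_total, 0, 24))
  phase_group <- rep(NA_real_, n_total)
  if (!is.null(config$phase_groups_h) && n_aligned > 0) {
    idx <- which(label == "aligned")
    phase_group[idx] <- config$phase_groups_h[
      ((seq_along(idx) - 1) %% length(config$phase_groups_h)) + 1]
    phase_global[idx] <- phase_group[idx]
  }

  amp_factor <- ifelse(label == "benchmark", config$benchmark_amplitude_factor,
                       ifelse(label == "decoy", config$decoy_amplitude_factor, 1))
  series <- list(); per_tissue <- list(); n_clipped <- 0L
  for (s in seq_along(tissues)) {
    bt <- with_seed(tissue_seed(config$seed, s), {
      list(baseline = pmax(0, stats::rnorm(n_total, config$baseline_mean,
                                           config$baseline_sd)),
           amp_raw = pmax(0.05 * config$amplitude_mean,
                          stats::rnorm(n_total, config$amplitude_mean,
                                       config$amplitude_sd)))
    })
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[ci]
      disp <- config$phase_dispersion_h[[cond]]
      gain <- config$amplitude_gain[[cond]]
      amp <- bt$amp_raw * amp_factor * ifelse(coherent, gain, 1)
      draws <- with_seed(cond_tissue_seed(config$seed, s, ci), {
        jitter <- stats::rnorm(n_total, 0, ifelse(label == "benchmark",
                                                  config$benchmark_dispersion_h, disp))
        uniform <- stats::runif(n_total, 0, 24)
        noise <- stats::rnorm(n_total * nt * nr, 0, config$noise_sd)
        list(jitter = jitter, uniform = uniform, noise = noise)
      })
      phase <- ifelse(coherent, (phase_global + draws$jitter) %% 24, draws$uniform)
      signal <- outer(seq_len(n_total), tp, function(g, t)
        bt$baseline[g] + amp[g] * cos(2 * pi * (t - phase[g]) / 24))
      reps <- array(rep(signal, nr), dim = c(n_total, nt, nr)) +
        array(draws$noise, dim = c(n_total, nt, nr))
      n_clipped <- n_clipped + sum(reps < 0)
      reps[reps < 0] <- 0
      avg <- rowMeans(reps, dims = 2)
      series[[paste(cond, tissues[s], sep = "|")]] <-
        tsexpr(tissues[s], cond, avg, timepoints_h = tp, genes = genes,
               replicate_averaged = TRUE)
      per_tissue[[length(per_tissue) + 1]] <- data.frame(
        condition = cond, tissue = tissues[s], gene = genes,
        phase_h = phase, amplitude = amp, baseline = bt$baseline,
        stringsAsFactors = FALSE)
    }
  }
  if (n_clipped > 0)
    cs_log(sprintf("generate_dataset: clipped %d negative simulated value(s) to 0",
                   n_clipped))
  truth <- list(
    genes = data.frame(gene = genes, label = label,
                       phase_global_h = phase_global,
                       phase_group_h = phase_group, stringsAsFactors = FALSE),
    per_tissue = do.call(rbind, per_tissue))
  dataset <- study_dataset(series,
    provenance = sprintf("circasync synthetic study (seed %d)", config$seed))
  list(dataset = dataset, truth = truth, n_clipped = n_clipped)
}

#' Benchmark gene list from a simulated ground truth
#'
#' Returns the designated clock-like benchmark genes (simulated with the
#' smallest phase dispersion and highest amplitude), optionally together with
#' the deliberately weak decoys that emulate low-ranked members of a curated
#' clock-gene list.
#'
#' @param truth The `truth` element of [generate_dataset()] output.
#' @param include_decoys Append the decoy genes (default `TRUE`).
#' @return A list: `genes` (all returned ids, strong first), `strong`,
#'   `decoys`.
#' @export
designate_benchmarks <- function(truth, include_decoys = TRUE) {
  strong <- truth$genes$gene[truth$genes$label == "benchmark"]
  decoys <- truth$genes$gene[truth$genes$label == "decoy"]
  if (!length(strong)) stopf("config error: no benchmark genes were simulated")
  list(genes = c(strong, if (include_decoys) decoys), strong = strong,
       decoys = if (include_decoys) decoys else character(0))
}

#' Generate a synthetic hierarchical pathway annotation
#'
#' Assigns each gene 1-3 random term paths drawn from a small fixed hierarchy
#' (roots including the broad "Metabolism" category), mimicking the structure
#' of a curated mitochondrial pathway inventory. Used so the enrichment stage
#' of a fully synthetic pipeline run has an annotation universe; it carries
#' no biological meaning.
#'
#' @param genes Gene symbols to annotate.
#' @param seed Integer seed.
#' @return A list: `annotation` (a [gene_set_annotation()]) and `table` (the
#'   two-column `gene` / `pathways` data.frame it was parsed from).
#' @export
simulate_annotation <- function(genes, seed = 1) {
  paths <- c(
    "Metabolism > Lipid metabolism > Fatty acid oxidation",
    "Metabolism > Lipid metabolism > Phospholipid metabolism",
    "Metabolism > Carbohydrate metabolism > TCA cycle",
    "Metabolism > Amino acid metabolism > BCAA catabolism",
    "Metabolism > Cofactor metabolism > Coenzyme Q metabolism",
    "Metabolism > Cofactor metabolism > Heme synthesis",
    "OXPHOS > Complex I > CI subunits",
    "OXPHOS > Complex V > CV assembly",
    "Central dogma > mtRNA metabolism > mtRNA processing",
    "Central dogma > mtDNA maintenance > mtDNA replication",
    "Mitochondrial dynamics and surveillance > Fission > Fission factors",
    "Mitochondrial dynamics and surveillance > Mitophagy > Receptor-mediated mitophagy",
    "Signaling > Calcium homeostasis > Calcium uptake",
    "Protein import and sorting > TIM23 pathway > Presequence import")
  tab <- with_seed(seed, {
    data.frame(gene = genes, pathways = vapply(genes, function(g) {
      k <- sample(1:3, 1)
      paste(sample(paths, k), collapse = " ; ")
    }, ""), stringsAsFactors = FALSE)
  })
  list(annotation = parse_term_paths(tab), table = tab)
}
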
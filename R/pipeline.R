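PIPELINE_STAGES <- c("simulate", "prepare", "intra", "inter", "global",
                     "pathways", "amplitude")

stage_requires <- list(
  prepare = "simulate", intra = "prepare", inter = "prepare",
  global = "prepare", pathways = "global", amplitude = "global")

#' Run the full cross-tissue coordination pipeline on synthetic data
#'
#' Orchestrates simulate -> prepare -> intra -> inter -> global -> pathways ->
#' amplitude, writing every stage's outputs as plain TSV/JSON under `out_dir`
#' plus a JSON run manifest. All randomness flows from the simulation
#' config's seed; rerunning with the same config produces byte-identical
#' outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim A [sim_config()] describing the synthetic study.
#' @param stages Stages to run (default all; each stage requires its
#'   upstream stage in the same run).
#' @param alpha Significance level for pair counting and t-tests.
#' @param threshold_strategy,manual_threshold Passed to
#'   [calibrate_threshold()].
#' @param calibration_condition Condition whose benchmark scores calibrate
#'   the clock-like threshold (default the first condition).
#' @param cut_height,profile_mode Passed to [wave_clusters()].
#' @param inter_mode Passed to [inter_pair_summaries()].
#' @param k Ranking depth for term enrichment.
#' @return The run manifest, invisibly (a named list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(out_dir, sim = sim_config(),
                         stages = PIPELINE_STAGES, alpha = 0.05,
                         threshold_strategy = "largest_gap",
                         manual_threshold = NULL,
                         calibration_condition = NULL,
                         cut_height = 1.0, profile_mode = "concatenated",
                         inter_mode = "all_pairs", k = 5) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  for (st in stages) {
    need <- stage_requires[[st]]
    if (!is.null(need) && !need %in% stages)
      stopf("stage '%s' requires stage '%s' in the same run", st, need)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("circasync")),
                   seed = sim$seed, alpha = alpha,
                   threshold_strategy = threshold_strategy,
                   cut_height = cut_height, profile_mode = profile_mode,
                   inter_mode = inter_mode, k = k,
                   parameters = unclass(sim)[setdiff(names(sim), "phase_groups_h")],
                   stages = list())
  env <- new.env()

  if ("simulate" %in% stages) {
    gen <- generate_dataset(sim)
    env$dataset_raw <- gen$dataset; env$truth <- gen$truth
    env$benchmarks <- if (sim$benchmark_n > 0) designate_benchmarks(gen$truth)
    ann <- simulate_annotation(gen$truth$genes$gene, seed = sim$seed)
    env$annotation <- ann$annotation
    for (key in names(gen$dataset$series)) {
      s <- gen$dataset$series[[key]]
      write_expression_table(s, file.path(out_dir,
        sprintf("expr_%s_%s.tsv", s$condition, s$tissue)))
    }
    write_tsv(gen$truth$genes, file.path(out_dir, "truth_genes.tsv"))
    write_tsv(ann$table, file.path(out_dir, "annotation_synthetic.tsv"))
    manifest$stages$simulate <- list(n_series = length(gen$dataset$series),
                                     n_genes = nrow(gen$truth$genes),
                                     n_clipped = gen$n_clipped)
  }

  if ("prepare" %in% stages) {
    env$dataset <- map_series(env$dataset_raw, filter_detected)
    env$dataset_norm <- suppressWarnings(map_series(env$dataset, minmax_normalize))
    manifest$stages$prepare <- list(
      n_genes_retained = length(env$dataset$series[[1]]$genes))
  }

  if ("intra" %in% stages) {
    mats <- lapply(env$dataset_norm$series, correlation_matrix)
    env$intra_matrices <- mats
    summ <- do.call(rbind, lapply(names(mats), function(key) {
      s <- env$dataset_norm$series[[key]]
      cs <- summarize_matrix(mats[[key]], alpha)
      data.frame(condition = s$condition, tissue = s$tissue,
                 mean_abs_r = cs$mean_abs_r, n_significant = cs$n_significant,
                 n_pairs = cs$n_pairs, stringsAsFactors = FALSE)
    }))
    summ <- summ[order(summ$condition, summ$tissue), ]
    write_tsv(summ, file.path(out_dir, "intra_summary.tsv"))
    env$intra_summary <- summ
    conds <- env$dataset_norm$conditions
    if (length(conds) >= 2) {
      cmp <- do.call(rbind, lapply(sort(env$dataset_norm$tissues), function(t) {
        cc <- compare_intra(mats[[paste(conds[1], t, sep = "|")]],
                            mats[[paste(conds[2], t, sep = "|")]], alpha = alpha)
        data.frame(tissue = t, metric = cc$metric, valueA = cc$valueA,
                   valueB = cc$valueB, delta = cc$delta, t = cc$t,
                   p_value = cc$p_value, classification = cc$classification,
                   stringsAsFactors = FALSE)
      }))
      write_tsv(cmp, file.path(out_dir, "intra_comparison.tsv"))
    }
    manifest$stages$intra <- list(n_matrices = length(mats))
  }

  if ("inter" %in% stages) {
    conds <- env$dataset_norm$conditions
    pair_list <- lapply(conds, function(cond)
      inter_pair_summaries(env$dataset_norm, cond, mode = inter_mode, alpha = alpha))
    names(pair_list) <- conds
    pairs_df <- do.call(rbind, lapply(conds, function(cond)
      cbind(condition = cond, pair_list[[cond]], stringsAsFactors = FALSE)))
    write_tsv(pairs_df, file.path(out_dir, "inter_pairs.tsv"))
    sig_df <- do.call(rbind, lapply(conds, function(cond)
      cbind(condition = cond, tissue_sigma(pair_list[[cond]]),
            stringsAsFactors = FALSE)))
    write_tsv(sig_df, file.path(out_dir, "inter_sigma.tsv"))
    if (length(conds) >= 2) {
      sA <- tissue_sigma(pair_list[[conds[1]]])
      sB <- tissue_sigma(pair_list[[conds[2]]])
      rel <- data.frame(tissue = sA$tissue,
                        relative_change = mapply(relative_change,
                                                 sA$sigma_abs_r, sB$sigma_abs_r),
                        stringsAsFactors = FALSE)
      write_tsv(rel, file.path(out_dir, "inter_relative_change.tsv"))
    }
    edges <- do.call(rbind, lapply(conds, function(cond)
      cbind(condition = cond, network_edges(pair_list[[cond]]),
            stringsAsFactors = FALSE)))
    write_tsv(edges, file.path(out_dir, "inter_edges.tsv"))
    manifest$stages$inter <- list(n_pairs = nrow(pair_list[[1]]))
  }

  if ("global" %in% stages) {
    conds <- env$dataset$conditions
    tabs <- lapply(conds, function(cond) score_table(env$dataset, cond))
    names(tabs) <- conds
    env$score_tables <- tabs
    score_df <- do.call(rbind, lapply(conds, function(cond)
      data.frame(condition = cond, gene = names(tabs[[cond]]$scores),
                 score = unname(tabs[[cond]]$scores),
                 n_pairs_used = unname(tabs[[cond]]$n_pairs_used),
                 stringsAsFactors = FALSE)))
    write_tsv(score_df, file.path(out_dir, "sync_scores.tsv"))
    cal_cond <- calibration_condition %||% conds[1]
    if (threshold_strategy == "manual") {
      cal <- calibrate_threshold(numeric(0), "manual",
                                 manual_threshold = manual_threshold)
    } else {
      bm <- env$benchmarks
      if (is.null(bm)) stopf("threshold calibration needs benchmark genes")
      bscores <- tabs[[cal_cond]]$scores[intersect(bm$genes,
                                                   names(tabs[[cal_cond]]$scores))]
      cal <- calibrate_threshold(bscores, threshold_strategy)
    }
    env$calibration <- cal
    jsonlite::write_json(
      list(strategy = cal$strategy, threshold = cal$threshold,
           calibration_condition = cal_cond,
           boundary_genes = cal$boundary_genes,
           benchmark_scores = as.list(cal$benchmark_scores)),
      file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
    sets <- lapply(conds, function(cond) global_set(tabs[[cond]], cal$threshold))
    names(sets) <- conds
    env$global_sets <- sets
    gs_df <- do.call(rbind, lapply(conds, function(cond)
      if (length(sets[[cond]]))
        data.frame(condition = cond, gene = sets[[cond]],
                   score = unname(tabs[[cond]]$scores[sets[[cond]]]),
                   stringsAsFactors = FALSE)))
    write_tsv(gs_df, file.path(out_dir, "global_sets.tsv"))
    if (length(conds) >= 2) {
      ov <- overlap_sets(sets[[conds[1]]], sets[[conds[2]]])
      jsonlite::write_json(ov, file.path(out_dir, "overlap.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    env$waves <- list()
    wave_rows <- list(); wf_rows <- list()
    for (cond in conds) {
      if (length(sets[[cond]]) < 2) next
      wc <- wave_clusters(sets[[cond]], env$dataset, cond,
                          cut_height = cut_height, profile_mode = profile_mode)
      env$waves[[cond]] <- wc
      wave_rows[[cond]] <- data.frame(condition = cond,
                                      gene = names(wc$labels),
                                      cluster = paste0("C", unname(wc$labels)),
                                      stringsAsFactors = FALSE)
      for (cl in names(wc$waveforms))
        wf_rows[[paste(cond, cl)]] <- cbind(condition = cond, cluster = cl,
                                            wc$waveforms[[cl]],
                                            stringsAsFactors = FALSE)
    }
    if (length(wave_rows))
      write_tsv(do.call(rbind, wave_rows), file.path(out_dir, "wave_clusters.tsv"))
    if (length(wf_rows))
      write_tsv(do.call(rbind, wf_rows), file.path(out_dir, "wave_waveforms.tsv"))
    manifest$stages$global <- list(
      threshold = cal$threshold,
      n_global = lapply(sets, length),
      n_waves = lapply(env$waves, `[[`, "n_clusters"))
  }

  if ("pathways" %in% stages) {
    enr_rows <- list()
    for (cond in names(env$waves)) {
      wc <- env$waves[[cond]]
      for (kk in sort(unique(wc$labels))) {
        members <- names(wc$labels)[wc$labels == kk]
        enr <- enrich_cluster(members, env$annotation,
                              cluster_id = sprintf("%s_C%d", cond, kk), k = k)
        if (!nrow(enr$table)) next
        enr_rows[[enr$cluster_id]] <- cbind(condition = cond,
                                            cluster = paste0("C", kk),
                                            enr$table,
                                            top_frequency = enr$table$term %in% enr$top_by_frequency,
                                            top_ratio = enr$table$term %in% enr$top_by_ratio,
                                            stringsAsFactors = FALSE)
      }
    }
    if (length(enr_rows))
      write_tsv(do.call(rbind, enr_rows), file.path(out_dir, "term_enrichment.tsv"))
    manifest$stages$pathways <- list(n_clusters = length(enr_rows))
  }

  if ("amplitude" %in% stages) {
    conds <- env$dataset$conditions
    ref <- conds[1]; cmp <- conds[length(conds)]
    top_gene <- names(env$score_tables[[cmp]]$scores)[1]
    amp_rows <- list(); ratios <- c()
    for (t in sort(env$dataset$tissues)) {
      recs <- lapply(conds, function(cond) {
        s <- get_series(env$dataset, cond, t)
        i <- match(top_gene, s$genes)
        if (is.na(i)) return(NULL)
        circadian_amplitude(s$values[i, ], s$timepoints_h)
      })
      names(recs) <- conds
      if (any(vapply(recs, is.null, TRUE))) next
      amp_rows[[t]] <- do.call(rbind, lapply(conds, function(cond)
        data.frame(gene = top_gene, tissue = t, condition = cond,
                   amplitude = recs[[cond]]$amplitude,
                   peak_time_h = recs[[cond]]$peak_time_h,
                   trough_time_h = recs[[cond]]$trough_time_h,
                   stringsAsFactors = FALSE)))
      if (recs[[ref]]$amplitude > 0)
        ratios[t] <- amplitude_change(recs[[ref]], recs[[cmp]], mode = "log2_ratio")
    }
    write_tsv(do.call(rbind, amp_rows), file.path(out_dir, "amplitude_tissues.tsv"))
    wbA <- rowMeans(gene_profiles(env$dataset, ref, top_gene))
    wbB <- rowMeans(gene_profiles(env$dataset, cmp, top_gene))
    tp <- env$dataset$series[[1]]$timepoints_h
    ampA <- circadian_amplitude(wbA, tp)
    ampB <- circadian_amplitude(wbB, tp)
    tt <- if (length(ratios) >= 2 && stats::sd(ratios) > 0)
      one_sample_ttest(ratios, 0) else NULL
    jsonlite::write_json(list(
      gene = top_gene,
      whole_body_amplitude = stats::setNames(
        list(ampA$amplitude, ampB$amplitude), c(ref, cmp)),
      amplitude_ratio = ampB$amplitude / ampA$amplitude,
      log2_ratio_test = tt),
      file.path(out_dir, "amplitude_summary.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$amplitude <- list(gene = top_gene, n_tissues = length(amp_rows))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
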
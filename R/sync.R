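#' Whole-body synchronization score of one gene
#'
#' The signed sum of same-gene Pearson correlations over all unordered pairs
#' of tissues in which the gene is present and non-constant. Signs are kept
#' (anti-phase tissue pairs subtract), so a gene perfectly in phase across T
#' tissues scores `choose(T, 2)`.
#'
#' @param gene Gene symbol.
#' @param dataset A prepared [study_dataset()].
#' @param condition Condition id.
#' @return A list with `score` and `n_pairs_used`.
#' @export
sync_score <- function(gene, dataset, condition) {
  profs <- gene_profiles(dataset, condition, gene)
  if (ncol(profs) < 2)
    stopf("gene '%s' usable in fewer than 2 tissues under '%s'", gene, condition)
  r <- stats::cor(profs)
  up <- r[upper.tri(r)]
  list(score = sum(up), n_pairs_used = length(up))
}

# timepoints x tissues matrix of one gene's profiles, keeping only tissues
# where the gene is present and non-constant.
gene_profiles <- function(dataset, condition, gene) {
  tissues <- sort(dataset$tissues)
  cols <- list()
  for (t in tissues) {
    s <- get_series(dataset, condition, t)
    i <- match(gene, s$genes)
    if (is.na(i)) next
    v <- s$values[i, ]
    if (stats::sd(v) == 0) next
    cols[[t]] <- v
  }
  do.call(cbind, cols) %||% matrix(0, 0, 0)
}

#' Whole-body synchronization scores for every eligible gene
#'
#' @param dataset A prepared [study_dataset()] (replicate-averaged, detection-
#'   and gene-set-filtered).
#' @param condition Condition id.
#' @param require_all_tissues If `TRUE` (default) only genes present and
#'   non-constant in every tissue are scored, so every score shares the
#'   `choose(T, 2)` pair ceiling; otherwise genes are scored over the tissue
#'   pairs available to them.
#' @return A `"sync_score_table"`: `condition`, `scores` (named numeric,
#'   descending), `n_pairs_used` (named integer), `tissues_used`.
#' @export
score_table <- function(dataset, condition, require_all_tissues = TRUE) {
  tissues <- sort(dataset$tissues)
  n_t <- length(tissues)
  if (n_t < 2) stopf("need at least 2 tissues")
  series <- lapply(tissues, function(t) get_series(dataset, condition, t))
  names(series) <- tissues
  usable <- lapply(series, function(s) {
    s$genes[apply(s$values, 1, stats::sd) > 0]
  })
  genes <- if (require_all_tissues) Reduce(intersect, usable)
           else unique(unlist(usable))
  genes <- sort(genes)
  eligible <- genes[vapply(genes, function(g)
    sum(vapply(usable, function(u) g %in% u, TRUE)) >= 2, TRUE)]
  if (!length(eligible)) stopf("no gene eligible for scoring")
  scores <- numeric(length(eligible)); npairs <- integer(length(eligible))
  for (k in seq_along(eligible)) {
    profs <- do.call(cbind, lapply(series, function(s) {
      i <- match(eligible[k], s$genes)
      if (is.na(i)) return(NULL)
      v <- s$values[i, ]
      if (stats::sd(v) == 0) NULL else v
    }))
    r <- stats::cor(profs)
    up <- r[upper.tri(r)]
    scores[k] <- sum(up); npairs[k] <- length(up)
  }
  names(scores) <- names(npairs) <- eligible
  ord <- order(-scores, eligible)
  structure(list(condition = condition, scores = scores[ord],
                 n_pairs_used = npairs[ord], tissues_used = tissues),
            class = "sync_score_table")
}

#' @export
print.sync_score_table <- function(x, ...) {
  cat(sprintf("<sync_score_table> %s: %d genes over %d tissues; score range [%.2f, %.2f]\n",
              x$condition, length(x$scores), length(x$tissues_used),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Calibrate the clock-like threshold from benchmark gene scores
#'
#' Locates the first or largest pronounced decline in the descending-sorted
#' synchronization scores of benchmark (core circadian) genes and places the
#' threshold at the midpoint of that drop; genes pass when score >= threshold.
#'
#' @param benchmark_scores Named numeric vector of benchmark-gene scores
#'   (>= 3).
#' @param strategy `"largest_gap"` (default): midpoint of the maximal drop
#'   between consecutive sorted scores. `"first_gap"`: midpoint of the first
#'   drop from the top exceeding `gap_factor` times the median gap, falling
#'   back to `largest_gap` when none qualifies. `"manual"`: use
#'   `manual_threshold` as-is.
#' @param gap_factor Multiplier on the median gap for `first_gap` (default 3).
#' @param manual_threshold Threshold value for `strategy = "manual"`.
#' @return A `"threshold_calibration"`: `benchmark_scores` (sorted
#'   descending), `strategy`, `threshold`, `boundary_genes` (the two genes
#'   flanking the detected drop; `NULL` for manual).
#' @export
calibrate_threshold <- function(benchmark_scores,
                                strategy = c("largest_gap", "first_gap", "manual"),
                                gap_factor = 3, manual_threshold = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "manual") {
    if (is.null(manual_threshold)) stopf("manual strategy needs manual_threshold")
    return(structure(list(benchmark_scores = sort(benchmark_scores, decreasing = TRUE),
                          strategy = strategy, threshold = manual_threshold,
                          boundary_genes = NULL),
                     class = "threshold_calibration"))
  }
  if (length(benchmark_scores) < 3) stopf("need at least 3 benchmark scores")
  s <- sort(benchmark_scores, decreasing = TRUE)
  gaps <- -diff(s)
  idx <- if (strategy == "largest_gap") which.max(gaps) else {
    q <- which(gaps > gap_factor * stats::median(gaps))
    if (length(q)) q[1] else which.max(gaps)
  }
  structure(list(benchmark_scores = s, strategy = strategy,
                 threshold = unname((s[idx] + s[idx + 1]) / 2),
                 boundary_genes = names(s)[c(idx, idx + 1)]),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("<threshold_calibration> strategy = %s, threshold = %.3f",
              x$strategy, x$threshold))
  if (!is.null(x$boundary_genes))
    cat(sprintf(" (drop between %s and %s)", x$boundary_genes[1], x$boundary_genes[2]))
  cat("\n")
  invisible(x)
}

#' Globally synchronized gene set at a threshold
#'
#' @param table A `"sync_score_table"`.
#' @param threshold Score cutoff; genes with `score >= threshold` pass.
#' @return Gene symbols sorted by descending score, alphabetical tie-break.
#' @export
global_set <- function(table, threshold) {
  s <- table$scores[table$scores >= threshold]
  names(s)[order(-s, names(s))]
}

#' Overlap of two gene sets
#'
#' @param setA,setB Character vectors of gene symbols.
#' @return A list: `n_shared`, `n_unique_A`, `n_unique_B`, and member vectors
#'   `shared`, `unique_A`, `unique_B`.
#' @export
overlap_sets <- function(setA, setB) {
  list(n_shared = length(intersect(setA, setB)),
       n_unique_A = length(setdiff(setA, setB)),
       n_unique_B = length(setdiff(setB, setA)),
       shared = sort(intersect(setA, setB)),
       unique_A = sort(setdiff(setA, setB)),
       unique_B = sort(setdiff(setB, setA)))
}

#' Whole-body expression waveform of one gene
#'
#' Per-timepoint mean and standard error of the gene's per-tissue (min-max
#' normalized) profiles, plus the per-tissue profiles ordered by peak time.
#'
#' @param gene Gene symbol (present in >= 2 tissues).
#' @param dataset A prepared [study_dataset()].
#' @param condition Condition id.
#' @param normalize Min-max normalize each tissue profile first (default).
#' @return A list: `waveform` (data.frame `timepoint_h`, `mean`, `sem`),
#'   `tissue_profiles` (tissues x timepoints matrix, rows ordered by peak
#'   time), `n_tissues`.
#' @export
whole_body_waveform <- function(gene, dataset, condition, normalize = TRUE) {
  profs <- gene_profiles(dataset, condition, gene)
  if (ncol(profs) < 2) stopf("gene '%s' present in fewer than 2 tissues", gene)
  tp <- get_series(dataset, condition, colnames(profs)[1])$timepoints_h
  if (normalize) profs <- apply(profs, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  m <- t(profs)  # tissues x timepoints
  peak <- apply(m, 1, which.max)
  m <- m[order(peak, rownames(m)), , drop = FALSE]
  colnames(m) <- paste0("ZT", tp)
  wf <- data.frame(timepoint_h = tp, mean = colMeans(m),
                   sem = apply(m, 2, stats::sd) / sqrt(nrow(m)), row.names = NULL)
  list(waveform = wf, tissue_profiles = m, n_tissues = nrow(m))
}

#' Cluster globally synchronized genes into temporal waves
#'
#' Complete-linkage clustering (dissimilarity `1 - r`, the same engine as the
#' intra-tissue heatmaps) of gene similarity, cut at a fixed dendrogram
#' height. Gene similarity is computed either on per-tissue min-max profiles
#' concatenated in a fixed tissue order (`"concatenated"`, default — robust to
#' anti-phase tissues) or on the mean whole-body waveform (`"whole_body"`).
#'
#' @param genes Globally synchronized gene set (>= 2 genes).
#' @param dataset A prepared [study_dataset()].
#' @param condition Condition id.
#' @param cut_height Dendrogram cut height on `1 - r` (default 1.0, i.e. the
#'   r = 0 boundary).
#' @param profile_mode `"concatenated"` or `"whole_body"`.
#' @return A `"wave_clustering"`: `labels` (named integer cluster per gene),
#'   `n_clusters`, `cut_height`, `profile_mode`, `hclust`, and `waveforms` — a
#'   per-cluster list of whole-body mean +/- SD waveform data.frames.
#' @export
wave_clusters <- function(genes, dataset, condition, cut_height = 1.0,
                          profile_mode = c("concatenated", "whole_body")) {
  profile_mode <- match.arg(profile_mode)
  if (length(genes) < 2) stopf("need at least 2 genes to cluster")
  tissues <- sort(dataset$tissues)
  series <- lapply(tissues, function(t) get_series(dataset, condition, t))
  names(series) <- tissues
  tp <- series[[1]]$timepoints_h
  feat <- list()
  for (g in genes) {
    segs <- lapply(series, function(s) {
      i <- match(g, s$genes)
      if (is.na(i)) return(NULL)
      v <- s$values[i, ]
      if (max(v) == min(v)) return(NULL)
      (v - min(v)) / (max(v) - min(v))
    })
    if (profile_mode == "concatenated") {
      if (any(vapply(segs, is.null, TRUE))) {
        warning(sprintf("gene '%s' unusable in some tissue(s); skipped", g),
                call. = FALSE)
        next
      }
      feat[[g]] <- unlist(segs, use.names = FALSE)
    } else {
      segs <- segs[!vapply(segs, is.null, TRUE)]
      if (length(segs) < 2) {
        warning(sprintf("gene '%s' unusable in some tissue(s); skipped", g),
                call. = FALSE)
        next
      }
      feat[[g]] <- colMeans(do.call(rbind, segs))
    }
  }
  if (length(feat) < 2) stopf("fewer than 2 usable genes for clustering")
  fm <- do.call(rbind, feat)
  r <- stats::cor(t(fm))
  hc <- stats::hclust(stats::as.dist(1 - r), method = "complete")
  labels <- stats::cutree(hc, h = cut_height)
  wf <- lapply(sort(unique(labels)), function(k) {
    members <- names(labels)[labels == k]
    prof <- t(vapply(members, function(g) {
      rowMeans(gene_profiles_norm(dataset, condition, g))
    }, numeric(length(tp))))
    data.frame(timepoint_h = tp, mean = colMeans(prof),
               sd = apply(prof, 2, stats::sd), n_genes = length(members))
  })
  names(wf) <- paste0("C", sort(unique(labels)))
  structure(list(labels = labels, n_clusters = length(unique(labels)),
                 cut_height = cut_height, profile_mode = profile_mode,
                 hclust = hc, waveforms = wf),
            class = "wave_clustering")
}

# timepoints x tissues matrix of min-max normalized profiles for one gene.
gene_profiles_norm <- function(dataset, condition, gene) {
  profs <- gene_profiles(dataset, condition, gene)
  apply(profs, 2, function(v) (v - min(v)) / (max(v) - min(v)))
}

#' @export
print.wave_clustering <- function(x, ...) {
  cat(sprintf("<wave_clustering> %d cluster(s) at cut height %.2f (%s profiles)\n",
              x$n_clusters, x$cut_height, x$profile_mode))
  print(table(x$labels))
  invisible(x)
}
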
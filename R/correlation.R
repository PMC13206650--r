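#' Pearson correlation of two temporal profiles
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return The sample Pearson coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("profiles differ in length")
  if (length(x) < 3) stopf("need at least 3 timepoints for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined for a constant profile; drop constant genes first")
  r <- stats::cor(x, y)
  max(-1, min(1, r))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against a
#' t distribution with `n - 2` degrees of freedom; `|r| = 1` returns 0.
#'
#' @param r Correlation coefficient(s), `|r| <= 1`. Vectorized.
#' @param n Number of timepoints (>= 3).
#' @return Two-tailed p-value(s) in `[0, 1]`.
#' @export
pearson_pvalue <- function(r, n) {
  if (n < 3) stopf("need n >= 3")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stopf("|r| must be <= 1")
  r <- pmax(-1, pmin(1, r))
  p <- ifelse(abs(r) == 1, 0,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2))
  pmin(p, 1)
}

#' Critical |r| for significance at a given alpha
#'
#' The smallest absolute correlation significant at level `alpha` (two-sided,
#' unadjusted) with `n` timepoints: the inversion of the t test used by
#' [pearson_pvalue()]. At `n = 12`, `alpha = 0.05` this is 0.576.
#'
#' @param n Number of timepoints (>= 3).
#' @param alpha Significance level.
#' @return The critical absolute correlation.
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (n < 3) stopf("need n >= 3")
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
  tcrit / sqrt(tcrit^2 + n - 2)
}

#' All-pairs gene-gene correlation matrix within one tissue
#'
#' @param series A replicate-averaged [tsexpr()] with constant genes removed
#'   (see [minmax_normalize()]).
#' @return An object of class `"corr_matrix"`: fields `genes`, `r` (symmetric,
#'   unit diagonal), `n_timepoints`.
#' @export
correlation_matrix <- function(series) {
  stopifnot(inherits(series, "tsexpr"), series$replicate_averaged)
  if (length(series$genes) < 2) stopf("need at least 2 genes")
  sds <- apply(series$values, 1, stats::sd)
  if (any(sds == 0))
    stopf("constant gene(s) present: %s; drop them before correlating",
          paste(utils::head(series$genes[sds == 0], 5), collapse = ", "))
  r <- stats::cor(t(series$values))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r <- (r + t(r)) / 2
  structure(list(genes = series$genes, r = r,
                 n_timepoints = length(series$timepoints_h)),
            class = "corr_matrix")
}

#' Summarize a correlation matrix: synchronization strength and pair counts
#'
#' `mean_abs_r` is the mean absolute correlation over unordered off-diagonal
#' gene pairs (set `include_diagonal = TRUE` for the diagonal-inclusive
#' reading); `n_significant` counts pairs with unadjusted two-sided p < alpha.
#'
#' @param matrix A `"corr_matrix"` from [correlation_matrix()].
#' @param alpha Significance level (default 0.05, unadjusted).
#' @param include_diagonal Include the unit diagonal in the average.
#' @return An object of class `"corr_summary"`: `mean_abs_r`, `n_significant`,
#'   `alpha`, `n_pairs`, `include_diagonal`, `n_timepoints`.
#' @export
summarize_matrix <- function(matrix, alpha = 0.05, include_diagonal = FALSE) {
  stopifnot(inherits(matrix, "corr_matrix"))
  up <- matrix$r[upper.tri(matrix$r)]
  n_pairs <- length(up)
  mean_abs <- if (include_diagonal) {
    (sum(abs(up)) * 2 + nrow(matrix$r)) / length(matrix$r)
  } else mean(abs(up))
  rc <- critical_r(matrix$n_timepoints, alpha)
  structure(list(mean_abs_r = mean_abs,
                 n_significant = sum(abs(up) > rc),
                 alpha = alpha, n_pairs = n_pairs,
                 include_diagonal = include_diagonal,
                 n_timepoints = matrix$n_timepoints),
            class = "corr_summary")
}

#' @export
print.corr_summary <- function(x, ...) {
  cat(sprintf("<corr_summary> mean |r| = %.4f; %d of %d pairs significant at alpha = %g\n",
              x$mean_abs_r, x$n_significant, x$n_pairs, x$alpha))
  invisible(x)
}

#' Complete-linkage ordering of a correlation matrix
#'
#' Agglomerates genes on the dissimilarity `d = 1 - r` with complete linkage
#' and returns the dendrogram with its leaf order, as used to arrange
#' correlation heatmaps and to define temporal waves.
#'
#' @param matrix A `"corr_matrix"`.
#' @return A list with `order` (gene symbols in leaf order) and `hclust` (the
#'   [stats::hclust()] tree).
#' @export
hierarchical_order <- function(matrix) {
  stopifnot(inherits(matrix, "corr_matrix"))
  d <- stats::as.dist(1 - matrix$r)
  hc <- stats::hclust(d, method = "complete")
  list(order = matrix$genes[hc$order], hclust = hc)
}

#' Mean +/- SD waveform of a gene cluster
#'
#' Per-timepoint mean and standard deviation across a subset of genes, on
#' min-max normalized profiles by default (the scale on which clusters are
#' defined).
#'
#' @param series A replicate-averaged [tsexpr()].
#' @param gene_subset Genes to summarize (must be present).
#' @param normalize Min-max normalize each gene first (default `TRUE`).
#' @return A data.frame with `timepoint_h`, `mean`, `sd`, `n_genes`.
#' @export
cluster_waveform <- function(series, gene_subset, normalize = TRUE) {
  if (!length(gene_subset)) stopf("gene_subset is empty")
  missing <- setdiff(gene_subset, series$genes)
  if (length(missing))
    stopf("gene(s) not in series: %s", paste(missing, collapse = ", "))
  s <- if (normalize) minmax_normalize(series) else series
  gene_subset <- intersect(gene_subset, s$genes)
  v <- s$values[gene_subset, , drop = FALSE]
  data.frame(timepoint_h = s$timepoints_h,
             mean = colMeans(v),
             sd = if (nrow(v) > 1) apply(v, 2, stats::sd) else rep(0, ncol(v)),
             n_genes = length(gene_subset))
}

#' Compare intra-tissue synchronization between two conditions
#'
#' Computes the difference on the chosen summary metric and an unpaired
#' two-tailed t-test on the two populations of off-diagonal absolute
#' correlations, then classifies the tissue as increased / unchanged /
#' decreased.
#'
#' @param matrixA,matrixB `"corr_matrix"` objects for the same tissue under
#'   two conditions. Mismatched gene universes are intersected (logged).
#' @param metric `"mean_abs_r"` or `"n_significant"`.
#' @param alpha Significance level for both pair counting and the t-test.
#' @return A list: `metric`, `valueA`, `valueB`, `delta` (B - A),
#'   `relative_change`, `t`, `p_value`, `classification`.
#' @export
compare_intra <- function(matrixA, matrixB, metric = c("mean_abs_r", "n_significant"),
                          alpha = 0.05) {
  metric <- match.arg(metric)
  shared <- intersect(matrixA$genes, matrixB$genes)
  if (length(shared) < length(matrixA$genes) || length(shared) < length(matrixB$genes))
    cs_log(sprintf("compare_intra: intersecting gene universes (%d shared)",
                   length(shared)))
  ia <- match(shared, matrixA$genes); ib <- match(shared, matrixB$genes)
  rA <- matrixA$r[ia, ia]; rB <- matrixB$r[ib, ib]
  absA <- abs(rA[upper.tri(rA)]); absB <- abs(rB[upper.tri(rB)])
  sA <- summarize_matrix(structure(list(genes = shared, r = rA,
                                        n_timepoints = matrixA$n_timepoints),
                                   class = "corr_matrix"), alpha)
  sB <- summarize_matrix(structure(list(genes = shared, r = rB,
                                        n_timepoints = matrixB$n_timepoints),
                                   class = "corr_matrix"), alpha)
  vA <- sA[[metric]]; vB <- sB[[metric]]
  tt <- unpaired_ttest(absA, absB)
  cls <- if (tt$p_value >= alpha) "unchanged" else if (vB > vA) "increased" else "decreased"
  list(metric = metric, valueA = vA, valueB = vB, delta = vB - vA,
       relative_change = if (vA != 0) (vB - vA) / vA else NA_real_,
       t = tt$t, p_value = tt$p_value, classification = cls)
}

#' Overlap of significant gene pairs between two conditions
#'
#' @param matrixA,matrixB `"corr_matrix"` objects on a common gene universe.
#' @param alpha Significance level.
#' @return A list with counts `n_shared`, `n_unique_A`, `n_unique_B` and the
#'   pair identity vectors (`"geneI|geneJ"`, i < j alphabetically).
#' @export
pair_overlap <- function(matrixA, matrixB, alpha = 0.05) {
  shared <- intersect(matrixA$genes, matrixB$genes)
  if (length(shared) < 2) stopf("need a common gene universe")
  sig_pairs <- function(m) {
    i <- match(shared, m$genes)
    r <- m$r[i, i]
    rc <- critical_r(m$n_timepoints, alpha)
    idx <- which(upper.tri(r) & abs(r) > rc, arr.ind = TRUE)
    g1 <- pmin(shared[idx[, 1]], shared[idx[, 2]])
    g2 <- pmax(shared[idx[, 1]], shared[idx[, 2]])
    paste(g1, g2, sep = "|")
  }
  pa <- sig_pairs(matrixA); pb <- sig_pairs(matrixB)
  list(n_shared = length(intersect(pa, pb)),
       n_unique_A = length(setdiff(pa, pb)),
       n_unique_B = length(setdiff(pb, pa)),
       shared = sort(intersect(pa, pb)),
       unique_A = sort(setdiff(pa, pb)),
       unique_B = sort(setdiff(pb, pa)))
}
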
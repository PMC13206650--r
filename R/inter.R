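#' Cross-correlation between the genes of two tissues
#'
#' In `all_pairs` mode, the full |genes A| x |genes B| Pearson matrix between
#' every temporal profile in tissue A and every profile in tissue B (the
#' inter-tissue analogue of [correlation_matrix()]). In `same_gene` mode, the
#' vector of correlations r(gene g in A, gene g in B) over shared genes —
#' the ingredient of the whole-body synchronization score.
#'
#' @param seriesA,seriesB Replicate-averaged [tsexpr()] objects on the same
#'   time grid, constant genes removed.
#' @param mode `"all_pairs"` (default) or `"same_gene"`.
#' @return For `all_pairs`, a `"cross_corr"` object (`genes_a`, `genes_b`,
#'   `r` matrix, `n_timepoints`, `mode`); for `same_gene` the same class with
#'   `r` a named vector over shared genes.
#' @export
cross_correlation_matrix <- function(seriesA, seriesB,
                                     mode = c("all_pairs", "same_gene")) {
  mode <- match.arg(mode)
  if (!isTRUE(all.equal(seriesA$timepoints_h, seriesB$timepoints_h)))
    stopf("time grids differ between tissues '%s' and '%s'",
          seriesA$tissue, seriesB$tissue)
  stopifnot(seriesA$replicate_averaged, seriesB$replicate_averaged)
  n <- length(seriesA$timepoints_h)
  if (mode == "all_pairs") {
    r <- stats::cor(t(seriesA$values), t(seriesB$values))
    r[r > 1] <- 1; r[r < -1] <- -1
    structure(list(genes_a = seriesA$genes, genes_b = seriesB$genes,
                   tissue_a = seriesA$tissue, tissue_b = seriesB$tissue,
                   r = r, n_timepoints = n, mode = mode),
              class = "cross_corr")
  } else {
    shared <- intersect(seriesA$genes, seriesB$genes)
    if (!length(shared)) stopf("no shared genes between '%s' and '%s'",
                               seriesA$tissue, seriesB$tissue)
    va <- seriesA$values[shared, , drop = FALSE]
    vb <- seriesB$values[shared, , drop = FALSE]
    r <- vapply(seq_along(shared), function(i) stats::cor(va[i, ], vb[i, ]), 0)
    r <- pmax(-1, pmin(1, r))
    names(r) <- shared
    structure(list(genes_a = shared, genes_b = shared,
                   tissue_a = seriesA$tissue, tissue_b = seriesB$tissue,
                   r = r, n_timepoints = n, mode = mode),
              class = "cross_corr")
  }
}

#' Summarize one tissue pair: synchronization strength and significant count
#'
#' @param xcorr A `"cross_corr"` from [cross_correlation_matrix()].
#' @param alpha Significance level (unadjusted).
#' @return A `"tissue_pair_summary"`: `tissue_a`, `tissue_b`, `mean_abs_r`,
#'   `n_significant`, `n_entries`, `mode`, `alpha`.
#' @export
summarize_pair <- function(xcorr, alpha = 0.05) {
  stopifnot(inherits(xcorr, "cross_corr"))
  entries <- as.numeric(xcorr$r)
  rc <- critical_r(xcorr$n_timepoints, alpha)
  structure(list(tissue_a = xcorr$tissue_a, tissue_b = xcorr$tissue_b,
                 mean_abs_r = mean(abs(entries)),
                 n_significant = sum(abs(entries) > rc),
                 n_entries = length(entries), mode = xcorr$mode,
                 alpha = alpha),
            class = "tissue_pair_summary")
}

#' Summarize every unordered tissue pair of one condition
#'
#' @param dataset A prepared [study_dataset()] (averaged, filtered,
#'   constant-free series).
#' @param condition Condition id.
#' @param mode Passed to [cross_correlation_matrix()].
#' @param alpha Significance level.
#' @return A data.frame with one row per unordered tissue pair: `tissue_a`,
#'   `tissue_b`, `mean_abs_r`, `n_significant`, `n_entries`, `mode`.
#' @export
inter_pair_summaries <- function(dataset, condition, mode = "all_pairs",
                                 alpha = 0.05) {
  tissues <- sort(dataset$tissues)
  if (length(tissues) < 2) stopf("need at least 2 tissues")
  rows <- list()
  for (i in seq_len(length(tissues) - 1)) {
    for (j in seq((i + 1), length(tissues))) {
      xc <- cross_correlation_matrix(get_series(dataset, condition, tissues[i]),
                                     get_series(dataset, condition, tissues[j]),
                                     mode = mode)
      s <- summarize_pair(xc, alpha)
      rows[[length(rows) + 1]] <- data.frame(
        tissue_a = s$tissue_a, tissue_b = s$tissue_b,
        mean_abs_r = s$mean_abs_r, n_significant = s$n_significant,
        n_entries = s$n_entries, mode = s$mode, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-tissue summed correlation strength (Sigma |r|)
#'
#' For each tissue, the sum of pair-level mean absolute correlations over all
#' pairs involving that tissue.
#'
#' @param pair_summaries A data.frame as returned by [inter_pair_summaries()]
#'   covering every unordered tissue pair.
#' @return A data.frame with `tissue`, `sigma_abs_r`, `n_pairs`.
#' @export
tissue_sigma <- function(pair_summaries) {
  tissues <- sort(unique(c(pair_summaries$tissue_a, pair_summaries$tissue_b)))
  expected <- choose(length(tissues), 2)
  if (nrow(pair_summaries) != expected) {
    have <- paste(pmin(pair_summaries$tissue_a, pair_summaries$tissue_b),
                  pmax(pair_summaries$tissue_a, pair_summaries$tissue_b), sep = "|")
    all_pairs <- utils::combn(tissues, 2)
    want <- paste(all_pairs[1, ], all_pairs[2, ], sep = "|")
    stopf("missing tissue pair(s): %s",
          paste(setdiff(want, have), collapse = ", "))
  }
  sig <- vapply(tissues, function(t) {
    sum(pair_summaries$mean_abs_r[pair_summaries$tissue_a == t |
                                    pair_summaries$tissue_b == t])
  }, 0)
  data.frame(tissue = tissues, sigma_abs_r = sig,
             n_pairs = length(tissues) - 1L, stringsAsFactors = FALSE)
}

#' Relative change between two condition-level values
#'
#' Default is the signed fraction `(B - A) / A`; `mode = "ratio"` returns
#' `B / A`.
#'
#' @param valueA,valueB Values under the reference and comparison condition
#'   (e.g. ALF then TRF); `valueA` must be nonzero.
#' @param mode `"fraction"` (default) or `"ratio"`.
#' @return The relative change.
#' @export
relative_change <- function(valueA, valueB, mode = c("fraction", "ratio")) {
  mode <- match.arg(mode)
  if (valueA == 0) stopf("relative change undefined: reference value is 0")
  if (mode == "fraction") (valueB - valueA) / valueA else valueB / valueA
}

#' Export tissue-pair summaries as a network edge table
#'
#' One edge per unordered tissue pair, importable by external graph tools
#' (edge weight = synchronization strength, edge count = significant pairs).
#'
#' @param pair_summaries A data.frame from [inter_pair_summaries()].
#' @return A data.frame with `tissue_a`, `tissue_b`, `mean_abs_r`,
#'   `n_significant`.
#' @export
network_edges <- function(pair_summaries) {
  pair_summaries[, c("tissue_a", "tissue_b", "mean_abs_r", "n_significant")]
}
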
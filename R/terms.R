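#' Construct a hierarchical pathway-term annotation
#'
#' Maps gene symbols to multisets of pathway-term strings (every hierarchy
#' level counted), with an exclusion list applied at counting time.
#'
#' @param gene_to_terms Named list: gene symbol -> character vector of terms
#'   (duplicates meaningful: one entry per occurrence in the source paths).
#' @param excluded_terms Terms removed from every counting operation
#'   (default `"Metabolism"`, a broad root category with little specificity).
#' @return A `"gene_set_annotation"`: `gene_to_terms`, `excluded_terms`,
#'   `universe_genes`.
#' @export
gene_set_annotation <- function(gene_to_terms, excluded_terms = "Metabolism") {
  stopifnot(is.list(gene_to_terms), !is.null(names(gene_to_terms)))
  gene_to_terms <- lapply(gene_to_terms, function(x) {
    x <- trimws(as.character(x))
    x[nzchar(x)]
  })
  structure(list(gene_to_terms = gene_to_terms,
                 excluded_terms = trimws(as.character(excluded_terms)),
                 universe_genes = names(gene_to_terms)),
            class = "gene_set_annotation")
}

#' Parse hierarchical term-path annotations
#'
#' Each annotation row carries a gene and one or more term paths (e.g.
#' `"Metabolism > Lipid metabolism > Fatty acid oxidation"`); every hierarchy
#' level of every path becomes one term occurrence for the gene, so a level
#' shared by two paths of one gene counts twice. Empty terms after trimming
#' are skipped with a warning.
#'
#' @param annotation A data.frame with columns `gene` and `pathways`, or a
#'   path to a TSV with those columns.
#' @param path_sep Separator between hierarchy levels (default `">"`).
#' @param multi_sep Separator between multiple paths of one gene (default
#'   `";"`).
#' @param excluded_terms Passed to [gene_set_annotation()].
#' @return A [gene_set_annotation()].
#' @export
parse_term_paths <- function(annotation, path_sep = ">", multi_sep = ";",
                             excluded_terms = "Metabolism") {
  if (is.character(annotation) && length(annotation) == 1)
    annotation <- utils::read.table(annotation, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("gene", "pathways") %in% colnames(annotation)))
  genes <- trimws(annotation$gene)
  gl <- lapply(seq_len(nrow(annotation)), function(i) {
    paths <- strsplit(annotation$pathways[i], multi_sep, fixed = TRUE)[[1]]
    terms <- unlist(lapply(paths, function(p)
      trimws(strsplit(p, path_sep, fixed = TRUE)[[1]])))
    empty <- !nzchar(terms)
    if (any(empty))
      warning(sprintf("gene '%s': skipped %d empty term(s)", genes[i], sum(empty)),
              call. = FALSE)
    terms[!empty]
  })
  names(gl) <- genes
  if (anyDuplicated(genes)) {  # merge rows for the same gene
    merged <- lapply(split(gl, genes), function(x) unlist(x, use.names = FALSE))
    gl <- merged[unique(genes)]
  }
  gene_set_annotation(gl, excluded_terms = excluded_terms)
}

term_multiset <- function(genes, annotation, dedupe = FALSE) {
  terms <- unlist(lapply(genes, function(g) {
    tt <- annotation$gene_to_terms[[g]]
    if (is.null(tt)) {
      cs_log(sprintf("gene '%s' missing from annotation; counted as zero terms", g))
      return(character(0))
    }
    if (dedupe) unique(tt) else tt
  }), use.names = FALSE)
  terms[!terms %in% annotation$excluded_terms]
}

#' Term occurrence counts within a gene cluster
#'
#' @param cluster Gene symbols of one cluster.
#' @param annotation A [gene_set_annotation()].
#' @param dedupe Count each term at most once per gene (default `FALSE`:
#'   one count per occurrence in the gene's annotation paths).
#' @return Named integer vector of counts (excluded terms removed), sorted by
#'   decreasing count then alphabetically.
#' @export
term_frequency <- function(cluster, annotation, dedupe = FALSE) {
  terms <- term_multiset(cluster, annotation, dedupe)
  if (!length(terms)) return(stats::setNames(integer(0), character(0)))
  tab <- table(terms)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

#' Term ratios of a cluster against the annotation universe
#'
#' For every term occurring in the cluster, the cluster occurrence count
#' divided by the term's total occurrence count across the whole annotation
#' universe.
#'
#' @inheritParams term_frequency
#' @return Named numeric vector of ratios in `(0, 1]`.
#' @export
term_ratio <- function(cluster, annotation, dedupe = FALSE) {
  cl <- term_frequency(cluster, annotation, dedupe)
  uni <- term_frequency(annotation$universe_genes, annotation, dedupe)
  miss <- setdiff(names(cl), names(uni))
  if (length(miss))
    stopf("term(s) with zero universe count but positive cluster count: %s",
          paste(miss, collapse = ", "))
  cl / uni[names(cl)]
}

#' Full term enrichment of one cluster
#'
#' @inheritParams term_frequency
#' @param cluster_id Identifier stamped on the result.
#' @param k Ranking depth for [top_terms()] (default 5).
#' @return A `"term_enrichment"`: `cluster_id`, `table` (data.frame `term`,
#'   `cluster_count`, `universe_count`, `ratio`), `top_by_frequency`,
#'   `top_by_ratio`, `excluded`.
#' @export
enrich_cluster <- function(cluster, annotation, cluster_id = "C1", k = 5,
                           dedupe = FALSE) {
  freq <- term_frequency(cluster, annotation, dedupe)
  uni <- term_frequency(annotation$universe_genes, annotation, dedupe)
  tab <- data.frame(term = names(freq),
                    cluster_count = as.integer(freq),
                    universe_count = as.integer(uni[names(freq)]),
                    stringsAsFactors = FALSE)
  tab$ratio <- tab$cluster_count / tab$universe_count
  enr <- structure(list(cluster_id = cluster_id, table = tab,
                        excluded = annotation$excluded_terms),
                   class = "term_enrichment")
  enr$top_by_frequency <- top_terms(enr, k, metric = "frequency")
  enr$top_by_ratio <- top_terms(enr, k, metric = "ratio")
  enr
}

#' Top-k terms of an enrichment by frequency or ratio
#'
#' Ties on the chosen metric break by the other metric (descending), then
#' alphabetically.
#'
#' @param enrichment A `"term_enrichment"` from [enrich_cluster()].
#' @param k Number of terms (default 5); fewer are returned when the cluster
#'   has fewer annotated terms.
#' @param metric `"frequency"` or `"ratio"`.
#' @return Character vector of at most `k` terms.
#' @export
top_terms <- function(enrichment, k = 5, metric = c("frequency", "ratio")) {
  metric <- match.arg(metric)
  stopifnot(k >= 1)
  tab <- enrichment$table
  if (!nrow(tab)) return(character(0))
  ord <- if (metric == "frequency")
    order(-tab$cluster_count, -tab$ratio, tab$term)
  else
    order(-tab$ratio, -tab$cluster_count, tab$term)
  utils::head(tab$term[ord], k)
}

#' @export
print.term_enrichment <- function(x, ...) {
  cat(sprintf("<term_enrichment> %s: %d term(s); top by frequency: %s\n",
              x$cluster_id, nrow(x$table),
              paste(x$top_by_frequency, collapse = ", ")))
  invisible(x)
}
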
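#' Construct a multi-condition, multi-tissue study dataset
#'
#' Bundles one [tsexpr()] per (condition, tissue) pair on a shared time grid.
#'
#' @param series A list of [tsexpr()] objects.
#' @param provenance Free-text source record.
#' @return An object of class `"study_dataset"` with fields `conditions`,
#'   `tissues`, `series` (named `"<condition>|<tissue>"`), `provenance`.
#' @export
study_dataset <- function(series, provenance = "") {
  stopifnot(length(series) >= 1, all(vapply(series, inherits, TRUE, "tsexpr")))
  conditions <- unique(vapply(series, `[[`, "", "condition"))
  tissues <- unique(vapply(series, `[[`, "", "tissue"))
  names(series) <- vapply(series, function(s) paste(s$condition, s$tissue, sep = "|"), "")
  if (anyDuplicated(names(series))) stopf("duplicate (condition, tissue) series")
  for (cond in conditions) {
    grids <- lapply(series[startsWith(names(series), paste0(cond, "|"))],
                    `[[`, "timepoints_h")
    if (length(unique(lapply(grids, as.numeric))) > 1)
      stopf("series within condition '%s' do not share one time grid", cond)
  }
  structure(list(conditions = conditions, tissues = tissues,
                 series = series, provenance = provenance),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d condition(s) x %d tissue(s), %d series\n",
              length(x$conditions), length(x$tissues), length(x$series)))
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Fetch one series from a dataset
#' @param dataset A [study_dataset()].
#' @param condition,tissue Identifiers.
#' @return The matching [tsexpr()].
#' @export
get_series <- function(dataset, condition, tissue) {
  key <- paste(condition, tissue, sep = "|")
  s <- dataset$series[[key]]
  if (is.null(s)) stopf("no series for condition '%s', tissue '%s'", condition, tissue)
  s
}

#' Restrict a dataset to an annotated gene universe
#'
#' Keeps, in every tissue, only the genes present in the annotation universe
#' (e.g. a mitochondrial gene inventory), preserving input gene order.
#'
#' @param dataset A [study_dataset()].
#' @param annotation A [gene_set_annotation()] (or any list with a
#'   `universe_genes` character vector).
#' @return The filtered [study_dataset()]; per-tissue retained counts logged.
#' @export
filter_gene_set <- function(dataset, annotation) {
  universe <- annotation$universe_genes
  if (!length(universe)) stopf("annotation universe is empty")
  out <- lapply(dataset$series, function(s) {
    keep <- s$genes %in% universe
    if (!any(keep))
      stopf("no overlap between tissue '%s' genes and the annotation universe",
            s$tissue)
    cs_log(sprintf("filter_gene_set [%s/%s]: retained %d of %d genes",
                   s$condition, s$tissue, sum(keep), length(keep)))
    tsexpr(s$tissue, s$condition, s$values[keep, , drop = FALSE],
           s$timepoints_h, genes = s$genes[keep],
           replicate_averaged = s$replicate_averaged,
           col_time = s$col_time, col_rep = s$col_rep)
  })
  study_dataset(out, provenance = dataset$provenance)
}

#' Apply a per-series transformation across a whole dataset
#' @param dataset A [study_dataset()].
#' @param fn Function mapping a [tsexpr()] to a [tsexpr()].
#' @param ... Passed to `fn`.
#' @return The transformed [study_dataset()].
#' @export
map_series <- function(dataset, fn, ...) {
  study_dataset(lapply(dataset$series, fn, ...), provenance = dataset$provenance)
}
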
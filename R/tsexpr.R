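#' Construct a single-tissue circadian expression time series
#'
#' The basic container of the package: one gene-by-timepoint expression matrix
#' for one tissue under one feeding condition, sampled within a single 24-h
#' cycle. Replicate-level data are held with one column per (timepoint,
#' replicate); [average_replicates()] collapses them to one column per
#' timepoint.
#'
#' @param tissue Tissue identifier (e.g. `"liver"`).
#' @param condition Condition identifier (e.g. `"ALF"`, `"TRF"`).
#' @param values Numeric matrix, genes in rows. For replicate-averaged data the
#'   columns are the timepoints; for replicate-level data there is one column
#'   per (timepoint, replicate) pair described by `col_time` / `col_rep`.
#' @param timepoints_h Strictly increasing clock times in hours, all in
#'   `[0, 24)`, at least 3 of them.
#' @param genes Gene symbols, unique, one per row of `values`. Defaults to the
#'   rownames of `values`.
#' @param replicate_averaged Logical; `TRUE` when `values` has exactly one
#'   column per timepoint holding the replicate mean.
#' @param col_time,col_rep For replicate-level data, the timepoint (hours) and
#'   replicate index of each column of `values`.
#' @param validate Run invariant checks (default `TRUE`).
#' @return An object of class `"tsexpr"`.
#' @export
tsexpr <- function(tissue, condition, values, timepoints_h,
                   genes = rownames(values), replicate_averaged = TRUE,
                   col_time = NULL, col_rep = NULL, validate = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  genes <- trimws(as.character(genes))
  timepoints_h <- as.numeric(timepoints_h)
  if (replicate_averaged) {
    col_time <- timepoints_h
    col_rep <- rep(1L, length(timepoints_h))
  }
  rownames(values) <- genes
  obj <- structure(list(
    tissue = as.character(tissue),
    condition = as.character(condition),
    genes = genes,
    timepoints_h = timepoints_h,
    values = values,
    replicate_averaged = isTRUE(replicate_averaged),
    col_time = as.numeric(col_time),
    col_rep = as.integer(col_rep)
  ), class = "tsexpr")
  if (validate) validate_tsexpr(obj)
  obj
}

validate_tsexpr <- function(x) {
  tp <- x$timepoints_h
  if (length(tp) < 3) stopf("need at least 3 timepoints, got %d", length(tp))
  if (any(diff(tp) <= 0)) stopf("timepoints_h must be strictly increasing")
  if (any(tp < 0 | tp >= 24)) stopf("timepoints_h must lie in [0, 24)")
  if (anyDuplicated(x$genes))
    stopf("duplicate gene symbols: %s",
          paste(unique(x$genes[duplicated(x$genes)]), collapse = ", "))
  if (nrow(x$values) != length(x$genes))
    stopf("values has %d rows but %d genes", nrow(x$values), length(x$genes))
  if (ncol(x$values) != length(x$col_time))
    stopf("values has %d columns but %d column descriptors",
          ncol(x$values), length(x$col_time))
  if (!all(x$col_time %in% tp))
    stopf("column times not all present in timepoints_h")
  if (x$replicate_averaged && anyNA(x$values))
    stopf("replicate-averaged values must have no missing entries")
  invisible(x)
}

#' @export
print.tsexpr <- function(x, ...) {
  cat(sprintf("<tsexpr> %s / %s: %d genes x %d timepoints (%s)%s\n",
              x$condition, x$tissue, length(x$genes), length(x$timepoints_h),
              paste0("ZT", x$timepoints_h[1], "..ZT",
                     x$timepoints_h[length(x$timepoints_h)]),
              if (x$replicate_averaged) ", replicate-averaged"
              else sprintf(", %d replicate columns", ncol(x$values))))
  invisible(x)
}

ts_colnames <- function(x) {
  if (x$replicate_averaged) paste0("ZT", x$timepoints_h)
  else paste0("ZT", x$col_time, "_rep", x$col_rep)
}

#' Write an expression time series as a wide TSV
#'
#' One row per gene; a leading `gene` column then `ZT<h>` (averaged) or
#' `ZT<h>_rep<k>` (replicate-level) columns. The written table round-trips
#' exactly through [read_expression_table()].
#'
#' @param series A [tsexpr()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(series, path) {
  df <- data.frame(gene = series$genes, series$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", ts_colnames(series))
  write_tsv(df, path)
}

#' Read a delimited expression table
#'
#' Reads wide tables (genes in rows, `ZT<h>` or `ZT<h>_rep<k>` columns) or
#' long tables (columns `gene`, `timepoint_h`, `replicate`, `value`). Tables
#' with replicate columns are returned un-averaged with
#' `replicate_averaged = FALSE`; pass them through [average_replicates()].
#'
#' @param path Path to a delimited text file.
#' @param tissue,condition Identifiers to stamp on the result.
#' @param layout A list configuring the table layout. Fields (all optional):
#'   `format` (`"wide"` or `"long"`), `sep` (delimiter, default tab),
#'   `gene_col` (default `"gene"`), `time_regex` (regex with the hour in
#'   capture group 1 and the replicate, if any, in group 2; default matches
#'   `ZT<h>` and `ZT<h>_rep<k>`).
#' @return A [tsexpr()] object preserving input gene order.
#' @export
read_expression_table <- function(path, tissue = "tissue", condition = "cond",
                                  layout = list()) {
  fmt <- layout$format %||% "wide"
  sep <- layout$sep %||% "\t"
  gene_col <- layout$gene_col %||% "gene"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (fmt == "long") return(read_long_table(df, tissue, condition, gene_col))
  if (!gene_col %in% colnames(df))
    stopf("format error: no gene-identifier column '%s' in %s", gene_col, path)
  genes <- trimws(df[[gene_col]])
  if (anyDuplicated(genes))
    stopf("duplicate gene symbols in %s: %s", path,
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  rx <- layout$time_regex %||% "^ZT([0-9]+(?:\\.[0-9]+)?)(?:_rep([0-9]+))?$"
  value_cols <- setdiff(colnames(df), gene_col)
  m <- regmatches(value_cols, regexec(rx, value_cols))
  bad <- value_cols[vapply(m, length, 1L) == 0]
  if (length(bad))
    stopf("format error: column(s) not matching the timepoint pattern: %s",
          paste(bad, collapse = ", "))
  col_time <- vapply(m, function(g) as.numeric(g[2]), 0)
  col_rep <- vapply(m, function(g) {
    if (length(g) >= 3 && nzchar(g[3])) as.integer(g[3]) else 1L
  }, 1L)
  vals <- matrix(NA_real_, nrow(df), length(value_cols))
  for (j in seq_along(value_cols)) {
    v <- suppressWarnings(as.numeric(df[[value_cols[j]]]))
    if (anyNA(v) && !all(is.na(df[[value_cols[j]]]) == is.na(v))) {
      i <- which(is.na(v) & !is.na(df[[value_cols[j]]]))[1]
      stopf("parse error: non-numeric value '%s' at row %d, column '%s'",
            df[[value_cols[j]]][i], i, value_cols[j])
    }
    vals[, j] <- v
  }
  ord <- order(col_time, col_rep)
  vals <- vals[, ord, drop = FALSE]
  col_time <- col_time[ord]; col_rep <- col_rep[ord]
  averaged <- !anyDuplicated(col_time) && all(col_rep == 1L)
  tsexpr(tissue, condition, vals, timepoints_h = sort(unique(col_time)),
         genes = genes, replicate_averaged = FALSE,
         col_time = col_time, col_rep = col_rep)
}

read_long_table <- function(df, tissue, condition, gene_col) {
  need <- c(gene_col, "timepoint_h", "value")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopf("format error: long table missing column(s): %s",
          paste(miss, collapse = ", "))
  rep_col <- if ("replicate" %in% colnames(df)) as.integer(df$replicate)
             else rep(1L, nrow(df))
  genes <- unique(trimws(df[[gene_col]]))
  tp <- as.numeric(df$timepoint_h)
  keys <- paste(tp, rep_col, sep = "|")
  ukeys <- unique(keys[order(tp, rep_col)])
  vals <- matrix(NA_real_, length(genes), length(ukeys),
                 dimnames = list(genes, ukeys))
  v <- suppressWarnings(as.numeric(df$value))
  if (anyNA(v)) {
    i <- which(is.na(v))[1]
    stopf("parse error: non-numeric value '%s' at row %d, column 'value'",
          df$value[i], i)
  }
  vals[cbind(match(trimws(df[[gene_col]]), genes), match(keys, ukeys))] <- v
  parts <- strsplit(ukeys, "|", fixed = TRUE)
  col_time <- vapply(parts, function(p) as.numeric(p[1]), 0)
  col_rep <- vapply(parts, function(p) as.integer(p[2]), 1L)
  tsexpr(tissue, condition, vals, timepoints_h = sort(unique(col_time)),
         genes = genes, replicate_averaged = FALSE,
         col_time = col_time, col_rep = col_rep)
}

#' Average biological replicates per timepoint
#'
#' Collapses a replicate-level series to one column per timepoint holding the
#' arithmetic mean of its replicates. Unequal replicate counts across
#' timepoints are allowed (and logged); a timepoint with no replicate column
#' is an error.
#'
#' @param series A [tsexpr()] object (replicate-level or already averaged; the
#'   latter is returned with values unchanged).
#' @return A replicate-averaged [tsexpr()].
#' @export
average_replicates <- function(series) {
  tp <- sort(unique(series$col_time))
  counts <- vapply(tp, function(t) sum(series$col_time == t), 1L)
  if (any(counts == 0)) stopf("timepoint with zero replicates")
  if (length(unique(counts)) > 1)
    cs_log("unequal replicate counts across timepoints: ",
           paste(counts, collapse = ", "))
  out <- vapply(tp, function(t) {
    rowMeans(series$values[, series$col_time == t, drop = FALSE])
  }, numeric(length(series$genes)))
  out <- matrix(out, nrow = length(series$genes))
  tsexpr(series$tissue, series$condition, out, timepoints_h = tp,
         genes = series$genes, replicate_averaged = TRUE)
}

#' Retain genes detected at every timepoint
#'
#' A gene is "detected" when its (replicate-averaged) expression exceeds
#' `min_value` at a timepoint; by default a gene must be detected at every
#' timepoint to be kept.
#'
#' @param series A replicate-averaged [tsexpr()].
#' @param min_value Detection threshold (default 0, i.e. strictly positive).
#' @param require_all_timepoints If `TRUE` (default) a gene must exceed
#'   `min_value` at all timepoints; otherwise at any timepoint.
#' @return The filtered [tsexpr()]; the retained count is logged and stored in
#'   `attr(, "n_retained")`.
#' @export
filter_detected <- function(series, min_value = 0, require_all_timepoints = TRUE) {
  stopifnot(series$replicate_averaged)
  det <- series$values > min_value
  keep <- if (require_all_timepoints) apply(det, 1, all) else apply(det, 1, any)
  if (!any(keep))
    stopf("all genes removed by detection filter (min_value = %g); review threshold",
          min_value)
  out <- tsexpr(series$tissue, series$condition,
                series$values[keep, , drop = FALSE], series$timepoints_h,
                genes = series$genes[keep], replicate_averaged = TRUE)
  cs_log(sprintf("filter_detected [%s/%s]: retained %d of %d genes",
                 series$condition, series$tissue, sum(keep), length(keep)))
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Min-max normalize each gene across time
#'
#' Maps every non-constant gene to `(x - min) / (max - min)` over its own
#' timepoints, so each gene spans exactly \[0, 1\]. Constant genes have no
#' defined Pearson correlation and are dropped with a warning. Intended only
#' for correlation/clustering paths; amplitude analyses use unscaled values.
#'
#' @param series A replicate-averaged [tsexpr()].
#' @return The normalized [tsexpr()] (constant genes removed).
#' @export
minmax_normalize <- function(series) {
  stopifnot(series$replicate_averaged)
  rng <- apply(series$values, 1, range)
  const <- rng[2, ] == rng[1, ]
  if (any(const))
    warning(sprintf("dropping %d constant gene(s) before normalization: %s",
                    sum(const),
                    paste(utils::head(series$genes[const], 5), collapse = ", ")),
            call. = FALSE)
  keep <- !const
  if (!any(keep)) stopf("all genes constant; nothing to normalize")
  v <- series$values[keep, , drop = FALSE]
  v <- (v - rng[1, keep]) / (rng[2, keep] - rng[1, keep])
  tsexpr(series$tissue, series$condition, v, series$timepoints_h,
         genes = series$genes[keep], replicate_averaged = TRUE)
}

# Drop constant genes without rescaling (used where raw units must be kept).
drop_constant_genes <- function(series) {
  rng <- apply(series$values, 1, range)
  keep <- rng[2, ] > rng[1, ]
  if (all(keep)) return(series)
  tsexpr(series$tissue, series$condition, series$values[keep, , drop = FALSE],
         series$timepoints_h, genes = series$genes[keep],
         replicate_averaged = series$replicate_averaged)
}
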
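#' Construct a two-class expression dataset
#'
#' The canonical in-memory container used throughout the package: a numeric
#' probes x samples matrix of log2-scale intensities together with a
#' tumor/normal class label per sample. "tumor" is the positive class in
#' every downstream metric.
#'
#' @param values numeric matrix, probes in rows, samples in columns. All
#'   entries must be finite (resolve missing values at load time, see
#'   [read_expression_tsv]).
#' @param labels character vector of per-sample classes, each `"tumor"` or
#'   `"normal"`, one per column of `values`.
#' @param probe_ids unique probe identifiers; defaults to `rownames(values)`.
#' @param sample_ids unique sample identifiers; defaults to
#'   `colnames(values)`.
#' @param gene_symbols optional named character vector mapping probe ids to
#'   gene symbols (annotation only; probes are never collapsed by gene).
#' @param meta free-form list of provenance key/values.
#'
#' @return An object of class `"expression_dataset"`: a list with elements
#'   `values`, `labels`, `probe_ids`, `sample_ids`, `gene_symbols`, `meta`.
#' @examples
#' m <- matrix(rnorm(20, 8), 4, 5,
#'             dimnames = list(paste0("p", 1:4), paste0("s", 1:5)))
#' ds <- expression_dataset(m, c("tumor", "tumor", "tumor", "normal", "normal"))
#' ds
#' @export
expression_dataset <- function(values, labels, probe_ids = rownames(values),
                               sample_ids = colnames(values),
                               gene_symbols = NULL, meta = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    mt_stop("'values' must be a numeric matrix (probes x samples)",
            "markertree_format_error")
  if (is.null(probe_ids) || is.null(sample_ids))
    mt_stop("probe and sample identifiers are required", "markertree_format_error")
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(probe_ids))
    mt_stop("row count of 'values' must equal length(probe_ids)",
            "markertree_format_error")
  if (ncol(values) != length(sample_ids))
    mt_stop("column count of 'values' must equal length(sample_ids)",
            "markertree_format_error")
  if (anyDuplicated(probe_ids))
    mt_stop(sprintf("duplicate probe id: '%s'",
                    probe_ids[duplicated(probe_ids)][1]),
            "markertree_format_error")
  if (anyDuplicated(sample_ids))
    mt_stop(sprintf("duplicate sample id: '%s'",
                    sample_ids[duplicated(sample_ids)][1]),
            "markertree_format_error")
  labels <- as.character(labels)
  if (length(labels) != length(sample_ids))
    mt_stop("one class label per sample is required", "markertree_label_error")
  bad <- setdiff(unique(labels), c("tumor", "normal"))
  if (length(bad))
    mt_stop(sprintf("labels must be 'tumor' or 'normal' (got '%s')", bad[1]),
            "markertree_label_error")
  if (!all(is.finite(values)))
    mt_stop("all expression values must be finite; resolve missing values at load time",
            "markertree_format_error")
  dimnames(values) <- list(probe_ids, sample_ids)
  if (!is.null(gene_symbols)) gene_symbols <- unlist(gene_symbols)
  structure(
    list(values = values, labels = labels, probe_ids = probe_ids,
         sample_ids = sample_ids, gene_symbols = gene_symbols, meta = meta),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d probes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "tumor"), sum(x$labels == "normal")))
  if (length(x$meta))
    cat("meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# Both classes must be present for anything that trains or tests.
assert_two_class <- function(ds) {
  if (!all(c("tumor", "normal") %in% ds$labels))
    mt_stop("dataset must contain at least one tumor and one normal sample",
            "markertree_label_error")
  invisible(ds)
}

# Resolve a label specification against sample ids: either a named vector
# (sample id -> class) or a positional vector of length n_samples.
resolve_labels <- function(label_spec, sample_ids) {
  if (is.null(label_spec))
    mt_stop("a class label for every sample is required", "markertree_label_error")
  label_spec <- unlist(label_spec)
  if (!is.null(names(label_spec)) && any(names(label_spec) != "")) {
    missing <- setdiff(sample_ids, names(label_spec))
    if (length(missing))
      mt_stop(sprintf("label_spec is missing sample '%s'", missing[1]),
              "markertree_label_error")
    as.character(label_spec[sample_ids])
  } else {
    if (length(label_spec) != length(sample_ids))
      mt_stop("positional label_spec must have one entry per sample",
              "markertree_label_error")
    as.character(label_spec)
  }
}

# Impute missing entries with the probe's per-class mean; errors if a
# probe/class combination has no observed value at all.
impute_class_mean <- function(values, labels) {
  for (cls in unique(labels)) {
    cols <- labels == cls
    block <- values[, cols, drop = FALSE]
    if (anyNA(block)) {
      rows <- which(rowSums(is.na(block)) > 0)
      for (r in rows) {
        v <- block[r, ]
        if (all(is.na(v)))
          mt_stop(sprintf("probe '%s' has no observed value in class '%s'",
                          rownames(values)[r], cls),
                  "markertree_parse_error")
        v[is.na(v)] <- mean(v, na.rm = TRUE)
        values[r, cols] <- v
      }
    }
  }
  values
}
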
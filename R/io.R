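#' Read a tab-delimited expression matrix
#'
#' Expects probes in rows and samples in columns: the first row holds the
#' sample ids, the first column the probe ids, and every remaining cell a
#' numeric log2-scale intensity. Values are taken verbatim unless
#' `log2 = TRUE`.
#'
#' @param path path to the tab-delimited file.
#' @param label_spec per-sample class assignment: either a named vector
#'   (sample id -> `"tumor"`/`"normal"`) or a positional vector, one entry
#'   per sample column.
#' @param log2 apply a log2 transform to the values after reading (use for
#'   raw-scale intensities). No automatic detection is attempted.
#' @param impute_missing if `TRUE`, blank/NA cells are imputed with the
#'   probe's per-class mean; by default any missing cell is an error.
#' @return An [expression_dataset].
#' @export
read_expression_tsv <- function(path, label_spec, log2 = FALSE,
                                impute_missing = FALSE) {
  if (!file.exists(path))
    mt_stop(sprintf("file not found: %s", path), "markertree_format_error")
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    mt_stop("expression table needs a probe-id column and >= 1 sample column",
            "markertree_format_error")
  probe_ids <- tab[[1]]
  sample_ids <- colnames(tab)[-1]
  raw <- as.matrix(tab[, -1, drop = FALSE])
  values <- parse_numeric_cells(raw, probe_ids, sample_ids,
                                allow_missing = impute_missing)
  labels <- resolve_labels(label_spec, sample_ids)
  if (impute_missing && anyNA(values)) {
    rownames(values) <- probe_ids
    values <- impute_class_mean(values, labels)
  }
  if (log2) {
    if (any(values <= 0))
      mt_stop("log2 transform requires strictly positive intensities",
              "markertree_domain_error")
    values <- log2(values)
  }
  expression_dataset(values, labels, probe_ids = probe_ids,
                     sample_ids = sample_ids,
                     meta = list(source = path, log2_applied = log2))
}

# Character matrix -> numeric, with a parse error that names the offending
# probe/sample cell. Blank and "NA" cells become NA (rejected unless
# allow_missing).
parse_numeric_cells <- function(raw, probe_ids, sample_ids, allow_missing) {
  is_blank <- is.na(raw) | raw == "" | raw == "NA"
  values <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(values) & !is_blank, arr.ind = TRUE)
  if (nrow(bad))
    mt_stop(sprintf("non-numeric value '%s' at probe '%s', sample '%s'",
                    raw[bad[1, 1], bad[1, 2]], probe_ids[bad[1, 1]],
                    sample_ids[bad[1, 2]]),
            "markertree_parse_error")
  if (!allow_missing) {
    miss <- which(is_blank, arr.ind = TRUE)
    if (nrow(miss))
      mt_stop(sprintf("missing value at probe '%s', sample '%s' (set impute_missing = TRUE to impute per-class means)",
                      probe_ids[miss[1, 1]], sample_ids[miss[1, 2]]),
              "markertree_parse_error")
  }
  values
}

#' Write an expression dataset as a tab-delimited matrix
#'
#' Inverse of [read_expression_tsv]: sample ids in the header row, probe
#' ids in the first column. Labels are not stored in the matrix; keep them
#' in a separate two-column TSV (see [write_labels_tsv]).
#'
#' @param ds an [expression_dataset].
#' @param path output path.
#' @export
write_expression_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  tab <- data.frame(probe_id = ds$probe_ids,
                    ds$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
write_labels_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  write.table(data.frame(sample_id = ds$sample_ids, label = ds$labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-label table (sample_id, label columns)
#' @param path path to a two-column TSV.
#' @return named character vector mapping sample id to class.
#' @export
read_labels_tsv <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(tab)))
    mt_stop("label table must have columns sample_id, label",
            "markertree_format_error")
  structure(tab$label, names = tab$sample_id)
}

#' Read a GEO series-matrix file
#'
#' Parses the expression table between the standard
#' `!series_matrix_table_begin` / `!series_matrix_table_end` marker lines;
#' `!`-prefixed header lines preceding the table are preserved verbatim in
#' `meta$series_header`.
#'
#' @inheritParams read_expression_tsv
#' @return An [expression_dataset].
#' @export
read_series_matrix <- function(path, label_spec, log2 = FALSE,
                               impute_missing = FALSE) {
  if (!file.exists(path))
    mt_stop(sprintf("file not found: %s", path), "markertree_format_error")
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
    mt_stop("series-matrix table markers (begin/end) not found or empty table",
            "markertree_format_error")
  header <- grep("^!", lines[seq_len(begin - 1L)], value = TRUE)
  block <- lines[(begin + 1L):(end - 1L)]
  cells <- strsplit(block, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    mt_stop(sprintf("ragged series-matrix table: line %d has %d fields, expected %d",
                    which(widths != widths[1])[1] + begin,
                    widths[widths != widths[1]][1], widths[1]),
            "markertree_parse_error")
  strip <- function(x) gsub('^"|"$', "", x)
  head_row <- strip(cells[[1]])
  sample_ids <- head_row[-1]
  body <- cells[-1]
  probe_ids <- strip(vapply(body, `[[`, "", 1L))
  raw <- t(vapply(body, function(r) strip(r[-1]),
                  character(length(sample_ids))))
  if (length(sample_ids) == 1L) raw <- matrix(raw, ncol = 1L)
  values <- parse_numeric_cells(raw, probe_ids, sample_ids,
                                allow_missing = impute_missing)
  labels <- resolve_labels(label_spec, sample_ids)
  if (impute_missing && anyNA(values)) {
    rownames(values) <- probe_ids
    values <- impute_class_mean(values, labels)
  }
  if (log2) values <- log2(values)
  expression_dataset(values, labels, probe_ids = probe_ids,
                     sample_ids = sample_ids,
                     meta = list(source = path, log2_applied = log2,
                                 series_header = header))
}

#' Serialize / restore pipeline artifacts
#'
#' Lossless round-trip serialization for the pipeline's result objects:
#' trees, rule sets, selection traces, cross-validation results,
#' differential-expression tables and datasets. Trees, traces and CV
#' results are stored as JSON; rule and DE tables as TSV; datasets as the
#' expression-matrix TSV (labels are not stored).
#'
#' @param obj a `c45_tree`, `c45_rules`, `sffs_trace`, `cv_result`,
#'   `diffexpr` or `expression_dataset` object.
#' @param path output (input) path.
#' @param format `"auto"` picks the natural format for the type.
#' @return `read_artifact` returns the restored object (for datasets, the
#'   bare matrix-with-ids is restored; labels must be resupplied).
#' @export
write_artifact <- function(obj, path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (inherits(obj, "c45_tree")) {
    write_json_artifact(tree_to_json(obj), path)
  } else if (inherits(obj, "c45_rules")) {
    write.table(rules_to_table(obj), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else if (inherits(obj, "sffs_trace")) {
    write_json_artifact(trace_to_json(obj), path)
  } else if (inherits(obj, "cv_result")) {
    write_json_artifact(cv_to_json(obj), path)
  } else if (inherits(obj, "diffexpr")) {
    write.table(de_table(obj), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else if (inherits(obj, "expression_dataset")) {
    write_expression_tsv(obj, path)
  } else {
    mt_stop(sprintf("cannot serialize object of class '%s'", class(obj)[1]),
            "markertree_usage_error")
  }
  invisible(path)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' @rdname write_artifact
#' @export
read_artifact <- function(path) {
  if (!file.exists(path))
    mt_stop(sprintf("file not found: %s", path), "markertree_format_error")
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*\\{", first)) {
    x <- jsonlite::read_json(path, simplifyVector = FALSE)
    kind <- x$artifact %||% ""
    return(switch(kind,
      c45_tree = tree_from_json(x),
      sffs_trace = trace_from_json(x),
      cv_result = cv_from_json(x),
      mt_stop(sprintf("unknown JSON artifact kind '%s'", kind),
              "markertree_usage_error")))
  }
  header <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (identical(header[1:4], c("conditions", "class", "covered",
                               "misclassified")))
    return(rules_from_table(read.delim(path, sep = "\t",
                                       colClasses = "character")))
  if (all(c("probe_id", "t_stat", "adj_p") %in% header))
    return(de_from_table(read.delim(path, sep = "\t",
                                    stringsAsFactors = FALSE)))
  mt_stop("unrecognized artifact file", "markertree_usage_error")
}

# --- tree JSON ---------------------------------------------------------

tree_to_json <- function(tree) {
  nodes <- tree$nodes
  as_node <- function(i) {
    if (nodes$leaf[i]) {
      list(class = nodes$class[i],
           n_covered = nodes$n_covered[i],
           n_misclassified = nodes$n_misclassified[i],
           n_normal = nodes$n_normal[i], n_tumor = nodes$n_tumor[i])
    } else {
      list(probe_id = nodes$probe_id[i], threshold = nodes$threshold[i],
           n_normal = nodes$n_normal[i], n_tumor = nodes$n_tumor[i],
           left = as_node(nodes$left[i]), right = as_node(nodes$right[i]))
    }
  }
  list(artifact = "c45_tree", classes = tree$classes,
       features = as.list(tree$features), n_train = tree$n_train,
       control = unclass(tree$control), root = as_node(1L))
}

tree_from_json <- function(x) {
  rows <- list()
  walk <- function(node) {
    if (!is.null(node$probe_id)) {
      self <- length(rows) + 1L
      rows[[self]] <<- list(leaf = FALSE, probe_id = node$probe_id,
                            threshold = node$threshold, left = NA_integer_,
                            right = NA_integer_, class = NA_character_,
                            n_normal = node$n_normal, n_tumor = node$n_tumor)
      l <- walk(node$left)
      r <- walk(node$right)
      rows[[self]]$left <<- l
      rows[[self]]$right <<- r
      self
    } else {
      rows[[length(rows) + 1L]] <<- list(leaf = TRUE, probe_id = NA_character_,
                                         threshold = NA_real_,
                                         left = NA_integer_, right = NA_integer_,
                                         class = node$class,
                                         n_normal = node$n_normal,
                                         n_tumor = node$n_tumor)
      length(rows)
    }
  }
  walk(x$root)
  nodes <- do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  nodes$n_covered <- nodes$n_normal + nodes$n_tumor
  nodes$n_misclassified <- ifelse(nodes$leaf,
    ifelse(nodes$class == "tumor", nodes$n_normal, nodes$n_tumor), NA_integer_)
  ctrl <- do.call(c45_control, x$control)
  new_c45_tree(nodes, features = unlist(x$features),
               classes = unlist(x$classes), control = ctrl,
               n_train = x$n_train)
}

# --- trace JSON --------------------------------------------------------

trace_to_json <- function(tr) {
  list(artifact = "sffs_trace",
       steps = lapply(seq_len(nrow(tr$steps)), function(i)
         as.list(tr$steps[i, ])),
       selected = as.list(tr$selected),
       params = list(patience = tr$patience, max_iter = tr$max_iter,
                     control = unclass(tr$control)))
}

trace_from_json <- function(x) {
  steps <- do.call(rbind, lapply(x$steps, function(s)
    data.frame(iteration = as.integer(s$iteration),
               n_candidates_evaluated = as.integer(s$n_candidates_evaluated),
               chosen_probe = s$chosen_probe,
               loocv_accuracy_after = as.numeric(s$loocv_accuracy_after),
               improved = as.logical(s$improved),
               stringsAsFactors = FALSE)))
  structure(list(steps = steps, selected = unlist(x$selected) %||% character(),
                 patience = x$params$patience, max_iter = x$params$max_iter,
                 control = do.call(c45_control, x$params$control)),
            class = "sffs_trace")
}

# --- cv JSON -----------------------------------------------------------

cv_to_json <- function(cv) {
  list(artifact = "cv_result", scheme = cv$scheme, k = cv$k, seed = cv$seed,
       predictions = lapply(seq_len(nrow(cv$predictions)), function(i)
         as.list(cv$predictions[i, ])),
       confusion = as.list(unclass(cv$confusion)),
       sensitivity = cv$sensitivity, specificity = cv$specificity,
       accuracy = cv$accuracy, notes = as.list(cv$notes))
}

cv_from_json <- function(x) {
  preds <- do.call(rbind, lapply(x$predictions, function(p)
    data.frame(sample_id = p$sample_id, truth = p$truth,
               predicted = p$predicted,
               fold = as.integer(p$fold), stringsAsFactors = FALSE)))
  cm <- structure(as.integer(unlist(x$confusion)),
                  names = names(x$confusion), class = "confusion_matrix")
  structure(list(scheme = x$scheme, k = x$k, seed = x$seed,
                 predictions = preds, confusion = cm,
                 sensitivity = null_as_na(x$sensitivity),
                 specificity = null_as_na(x$specificity),
                 accuracy = null_as_na(x$accuracy),
                 notes = unlist(x$notes) %||% character()),
            class = "cv_result")
}

null_as_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

# --- rules / DE tables -------------------------------------------------

rules_to_table <- function(rules) {
  data.frame(conditions = vapply(rules$conditions, format_conditions, ""),
             class = rules$class, covered = rules$covered,
             misclassified = rules$misclassified, stringsAsFactors = FALSE)
}

format_conditions <- function(cond) {
  if (!nrow(cond)) return("")
  paste(sprintf("%s %s %s", cond$probe_id, cond$op,
                sprintf("%.17g", cond$threshold)), collapse = " & ")
}

parse_conditions <- function(s) {
  if (is.na(s) || s == "")
    return(data.frame(probe_id = character(), op = character(),
                      threshold = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(s, " & ", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(.*) (<=|>) ([-+0-9.eE]+)$", parts))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    mt_stop(sprintf("cannot parse rule condition '%s'", parts[bad][1]),
            "markertree_parse_error")
  data.frame(probe_id = vapply(m, `[[`, "", 2L),
             op = vapply(m, `[[`, "", 3L),
             threshold = as.numeric(vapply(m, `[[`, "", 4L)),
             stringsAsFactors = FALSE)
}

rules_from_table <- function(tab) {
  new_c45_rules(conditions = lapply(tab$conditions, parse_conditions),
                class = as.character(tab$class),
                covered = as.integer(tab$covered),
                misclassified = as.integer(tab$misclassified))
}

de_table <- function(de) {
  out <- de$records
  out$kept <- out$probe_id %in% de$kept
  out
}

de_from_table <- function(tab) {
  kept <- tab$probe_id[as.logical(tab$kept)]
  tab$kept <- NULL
  structure(list(records = tab, kept = kept, alpha = NA_real_,
                 variant = NA_character_, paired = NA),
            class = "diffexpr")
}
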
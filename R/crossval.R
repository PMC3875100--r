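#' Confusion matrix with tumor as the positive class
#'
#' @param truth character vector of true classes (`"tumor"`/`"normal"`).
#' @param predicted character vector of predicted classes, same length.
#' @return An object of class `"confusion_matrix"`: named integer vector
#'   `c(tp, fp, fn, tn)`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    mt_stop("'truth' and 'predicted' must have equal length",
            "markertree_usage_error")
  structure(c(tp = sum(truth == "tumor" & predicted == "tumor"),
              fp = sum(truth == "normal" & predicted == "tumor"),
              fn = sum(truth == "tumor" & predicted == "normal"),
              tn = sum(truth == "normal" & predicted == "normal")),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(x[c("tp", "fn", "fp", "tn")], 2, 2, byrow = TRUE,
              dimnames = list(truth = c("tumor", "normal"),
                              predicted = c("tumor", "normal")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/(TP+FP+FN+TN)`, with tumor the positive class. A
#' metric whose denominator is zero is undefined and returned as `NA`
#' (never coerced to 0).
#'
#' @param cm a [confusion_matrix] (or named vector with tp/fp/fn/tn).
#' @return `list(sensitivity, specificity, accuracy)` as proportions.
#' @examples
#' classification_metrics(confusion_matrix(
#'   rep(c("tumor", "normal"), c(17, 17)),
#'   rep(c("tumor", "normal", "tumor", "normal"), c(15, 2, 1, 16))))
#' @export
classification_metrics <- function(cm) {
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       accuracy = ratio(tp + tn, tp + fp + fn + tn))
}

new_cv_result <- function(scheme, k, seed, predictions, notes = character()) {
  cm <- confusion_matrix(predictions$truth, predictions$predicted)
  m <- classification_metrics(cm)
  structure(list(scheme = scheme, k = k, seed = seed,
                 predictions = predictions, confusion = cm,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 accuracy = m$accuracy, notes = notes),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation (%d samples%s)\n", x$scheme,
              nrow(x$predictions),
              if (x$scheme == "kfold")
                sprintf(", k = %d, seed = %d", x$k, x$seed) else ""))
  cat(sprintf("accuracy %.4f, sensitivity %s, specificity %s\n", x$accuracy,
              format_metric(x$sensitivity), format_metric(x$specificity)))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

format_metric <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)

#' Leave-one-out cross-validation of a decision tree
#'
#' `n` deterministic folds in sample order: each sample is held out once,
#' a tree is grown (and pruned, per `control`) on the remaining `n - 1`
#' samples, and the held-out sample is predicted. Accuracy is the mean of
#' the `n` 0/1 outcomes, equivalently `(TP+TN)/n` of the accumulated
#' confusion matrix. A fold whose training part loses one class entirely
#' still proceeds (the tree degenerates to a majority leaf) and is noted
#' in the result.
#'
#' @param ds an [expression_dataset] with `n >= 3` and both classes.
#' @param features probe ids offered to the tree; default all.
#' @param control a [c45_control].
#' @return A `"cv_result"` with per-sample predictions, confusion matrix
#'   and metrics.
#' @export
loocv <- function(ds, features = NULL, control = c45_control()) {
  stopifnot(inherits(ds, "expression_dataset"))
  assert_two_class(ds)
  n <- ncol(ds$values)
  if (n < 3L)
    mt_stop("leave-one-out cross-validation needs at least 3 samples",
            "markertree_insufficient_data_error")
  features <- features %||% ds$probe_ids
  Xt <- t(ds$values[features, , drop = FALSE])
  y <- as.integer(ds$labels == "tumor")
  pred <- cpp_loocv(Xt, y, control$min_leaf,
                    control$criterion == "gain_ratio", control$mdl,
                    control$prune, control$confidence)
  classes <- c("normal", "tumor")
  notes <- character()
  lone <- names(which(table(ds$labels) == 1L))
  if (length(lone))
    notes <- sprintf("fold holding out the only '%s' sample trained on a single class (majority-leaf tree)",
                     lone)
  predictions <- data.frame(sample_id = ds$sample_ids, truth = ds$labels,
                            predicted = classes[pred + 1L],
                            fold = seq_len(n), stringsAsFactors = FALSE)
  new_cv_result("loocv", k = n, seed = NA_integer_, predictions, notes)
}

# Stratified fold ids: per-class seeded shuffle then round-robin, a pure
# function of (sample order, seed). Class proportions per fold differ by
# at most one sample.
fold_assignment <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    pos <- 0L
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      # continue the fold cycle across classes so k = n gives singleton
      # folds (exact LOOCV reduction) while stratification is kept
      folds[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
      pos <- pos + length(idx)
    }
  })
  folds
}

#' Stratified k-fold cross-validation of a decision tree
#'
#' Folds are stratified by class (per-class seeded shuffle, then
#' round-robin assignment) so class proportions are preserved to within
#' one sample. The assignment is a pure function of the sample order and
#' `seed`; the same seed always reproduces the same folds. With `k = n`
#' the partition coincides with [loocv] exactly.
#'
#' @inheritParams loocv
#' @param k number of folds, `2 <= k <= n` (default 10).
#' @param seed integer seed for the fold shuffle.
#' @return A `"cv_result"`.
#' @export
kfold_cv <- function(ds, features = NULL, control = c45_control(), k = 10L,
                     seed = 1L) {
  stopifnot(inherits(ds, "expression_dataset"))
  assert_two_class(ds)
  n <- ncol(ds$values)
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > n)
    mt_stop(sprintf("'k' must lie between 2 and the sample count (%d)", n),
            "markertree_usage_error")
  features <- features %||% ds$probe_ids
  Xt <- t(ds$values[features, , drop = FALSE])
  y <- as.integer(ds$labels == "tumor")
  folds <- fold_assignment(ds$labels, k, seed)
  classes <- c("normal", "tumor")
  predicted <- character(n)
  for (f in seq_len(k)) {
    test <- folds == f
    res <- cpp_grow(Xt[!test, , drop = FALSE], y[!test], control$min_leaf,
                    control$criterion == "gain_ratio", control$mdl,
                    control$prune, control$confidence)
    p <- cpp_predict(res$leaf, res$feature, res$threshold, res$left,
                     res$right, res$class, Xt[test, , drop = FALSE])
    predicted[test] <- classes[p + 1L]
  }
  predictions <- data.frame(sample_id = ds$sample_ids, truth = ds$labels,
                            predicted = predicted, fold = folds,
                            stringsAsFactors = FALSE)
  new_cv_result("kfold", k = k, seed = as.integer(seed), predictions)
}
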
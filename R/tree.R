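#' Control parameters for decision-tree induction
#'
#' @param confidence pruning confidence factor CF in (0, 1). Smaller values
#'   prune more aggressively; the default 0.25 is the conventional 25%
#'   setting of error-based pruning.
#' @param min_leaf minimum number of training samples per leaf (>= 1).
#' @param criterion split-ranking criterion: `"info_gain"` (default) ranks
#'   candidate thresholds by information gain; `"gain_ratio"` divides the
#'   gain by the split entropy. With binary threshold splits the two
#'   usually agree in ranking.
#' @param mdl apply the MDL correction for continuous thresholds during
#'   induction (default `TRUE`): the gain of a candidate split is charged
#'   `log2(d)/n` bits, `d` the number of admissible thresholds at the
#'   node. Without it, almost any threshold over continuous noise has
#'   positive gain and trees overfit severely.
#' @param prune apply error-based subtree replacement after growing.
#' @return A list of class `"c45_control"`.
#' @export
c45_control <- function(confidence = 0.25, min_leaf = 2L,
                        criterion = c("info_gain", "gain_ratio"),
                        mdl = TRUE, prune = TRUE) {
  criterion <- match.arg(criterion)
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1)
    mt_stop("'confidence' must lie strictly between 0 and 1",
            "markertree_domain_error")
  min_leaf <- as.integer(min_leaf)
  if (is.na(min_leaf) || min_leaf < 1L)
    mt_stop("'min_leaf' must be a positive integer", "markertree_domain_error")
  structure(list(confidence = confidence, min_leaf = min_leaf,
                 criterion = criterion, mdl = isTRUE(mdl),
                 prune = isTRUE(prune)),
            class = "c45_control")
}

#' Binary class entropy
#'
#' Shannon entropy in bits of a class-count vector:
#' `H = -sum (c/N) log2(c/N)`, with zero counts contributing zero.
#'
#' @param counts nonnegative integer class counts, not all zero.
#' @return entropy in bits.
#' @examples
#' entropy(c(5, 5))   # 1
#' entropy(c(10, 0))  # 0
#' @export
entropy <- function(counts) {
  if (any(counts < 0) || !all(is.finite(counts)))
    mt_stop("class counts must be finite and nonnegative",
            "markertree_domain_error")
  n <- sum(counts)
  if (n == 0)
    mt_stop("entropy is undefined for an empty node", "markertree_domain_error")
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Best binary threshold split of one continuous feature
#'
#' Evaluates every distinct observed value except the maximum as a
#' threshold partitioning samples into \{<= v\} and \{> v\}, and returns
#' the one maximizing the criterion.
#'
#' @param values numeric feature vector.
#' @param labels two-class label vector of the same length.
#' @param criterion `"info_gain"` or `"gain_ratio"`.
#' @param min_leaf smallest admissible child size.
#' @param mdl apply the continuous-threshold MDL correction (see
#'   [c45_control]); off by default so the returned score is the plain
#'   criterion value.
#' @return `list(threshold, score)`, or `NULL` when no admissible split has
#'   positive score (e.g. a constant feature).
#' @export
best_split <- function(values, labels, criterion = c("info_gain", "gain_ratio"),
                       min_leaf = 1L, mdl = FALSE) {
  criterion <- match.arg(criterion)
  if (length(values) != length(labels) || length(values) < 2L)
    mt_stop("'values' and 'labels' must have equal length >= 2",
            "markertree_usage_error")
  classes <- sort(unique(as.character(labels)))
  y <- as.integer(as.character(labels) == classes[length(classes)])
  s <- cpp_best_split(as.numeric(values), y, as.integer(min_leaf),
                      criterion == "gain_ratio", isTRUE(mdl))
  if (!s$found) return(NULL)
  list(threshold = s$threshold, score = s$score)
}

#' Pessimistic upper bound on a leaf's error rate
#'
#' The upper limit of the one-sided binomial confidence interval used by
#' error-based pruning: the largest error rate p satisfying
#' `P(X <= errors | n, p) = confidence`, i.e. the `1 - confidence` quantile
#' of `Beta(errors + 1, n - errors)` (exact inversion, not the historical
#' normal approximation). At `errors = 0` this reduces to the closed form
#' `1 - confidence^(1/n)`.
#'
#' @param errors observed misclassifications at the leaf (0 <= errors <= n).
#' @param n training samples covered by the leaf (>= 1).
#' @param confidence the confidence factor CF in (0, 1); default 0.25.
#' @return the upper error-rate bound in (0, 1].
#' @examples
#' ucf(0, 2)   # 1 - 0.25^(1/2) = 0.5
#' @export
ucf <- function(errors, n, confidence = 0.25) {
  if (any(n < 1) || any(errors < 0))
    mt_stop("need n >= 1 and errors >= 0", "markertree_domain_error")
  if (any(errors > n))
    mt_stop("'errors' cannot exceed 'n'", "markertree_domain_error")
  if (confidence <= 0 || confidence >= 1)
    mt_stop("'confidence' must lie strictly between 0 and 1",
            "markertree_domain_error")
  ifelse(errors >= n, 1, qbeta(1 - confidence, errors + 1, n - errors))
}

new_c45_tree <- function(nodes, features, classes, control, n_train,
                         call = NULL) {
  structure(list(nodes = nodes, features = features, classes = classes,
                 control = control, n_train = n_train, call = call),
            class = "c45_tree")
}

# Flat cpp node list -> nodes data.frame with domain labels.
nodes_from_cpp <- function(res, features, classes) {
  cls <- classes[res$class + 1L]
  n_cov <- res$n0 + res$n1
  data.frame(
    leaf = res$leaf,
    probe_id = ifelse(is.na(res$feature), NA_character_,
                      features[res$feature]),
    threshold = res$threshold,
    left = res$left, right = res$right,
    class = ifelse(res$leaf, cls, NA_character_),
    n_normal = res$n0, n_tumor = res$n1, n_covered = n_cov,
    n_misclassified = ifelse(res$leaf,
                             ifelse(cls == classes[2L], res$n0, res$n1),
                             NA_integer_),
    stringsAsFactors = FALSE)
}

#' Fit a C4.5-style decision tree on expression features
#'
#' Grows a binary-threshold tree by recursive partitioning: at each node
#' the feature/threshold pair maximizing the criterion is chosen, with the
#' threshold always an observed value at that node (`<=` descends left).
#' Growth stops at class purity, below `2 * min_leaf` samples, or when no
#' admissible split has positive score. Leaves are labelled by majority
#' rule (ties fall back to the parent's majority; a root tie takes the
#' lexicographically first class, `"normal"`). With `prune = TRUE`
#' error-based subtree replacement is applied bottom-up: a subtree is
#' collapsed to a leaf when the leaf's pessimistic error estimate
#' `N * ucf(E, N)` does not exceed the summed estimates of the subtree's
#' leaves (see [ucf]). No subtree raising is performed.
#'
#' @param ds an [expression_dataset]; a pure single-class input yields a
#'   single majority leaf.
#' @param features probe ids to offer as split candidates; default all.
#' @param control a [c45_control] object.
#' @return An object of class `"c45_tree"` with a `nodes` table (one row
#'   per node, preorder, row 1 = root) and the training leaf counts used
#'   by [extract_rules].
#' @seealso [predict.c45_tree], [extract_rules], [prune_tree]
#' @examples
#' sim <- simulate_expression(synthetic_spec(
#'   n_tumor = 15, n_normal = 15, n_probes = 20,
#'   planted = data.frame(role = "single_marker", delta = 4, f = NA),
#'   seed = 7))
#' fit <- c45(sim$dataset, features = sim$truth$planted$probe_id)
#' fit
#' @export
c45 <- function(ds, features = NULL, control = c45_control()) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!is.null(features) && length(features) == 0L)
    mt_stop("'features' must name at least one probe", "markertree_usage_error")
  features <- features %||% ds$probe_ids
  missing <- setdiff(features, ds$probe_ids)
  if (length(missing))
    mt_stop(sprintf("unknown probe id '%s'", missing[1]),
            "markertree_usage_error")
  classes <- c("normal", "tumor")
  Xt <- t(ds$values[features, , drop = FALSE])
  y <- as.integer(ds$labels == "tumor")
  res <- cpp_grow(Xt, y, control$min_leaf, control$criterion == "gain_ratio",
                  control$mdl, control$prune, control$confidence)
  new_c45_tree(nodes_from_cpp(res, features, classes),
               features = features, classes = classes, control = control,
               n_train = ncol(ds$values), call = match.call())
}

#' Error-based pruning of a fitted tree
#'
#' Reference R implementation of the bottom-up subtree-replacement rule
#' also applied by `c45(..., control = c45_control(prune = TRUE))`: a
#' subtree is replaced by its majority leaf whenever
#' `N * ucf(E, N, CF) <= sum over subtree leaves of n * ucf(e, n, CF)`.
#' Leaf counts are recomputed from the stored per-node training counts.
#'
#' @param tree a `c45_tree` (typically grown with `prune = FALSE`).
#' @param confidence the confidence factor; defaults to the tree's control.
#' @return the pruned `c45_tree`.
#' @export
prune_tree <- function(tree, confidence = tree$control$confidence) {
  stopifnot(inherits(tree, "c45_tree"))
  nodes <- tree$nodes
  classes <- tree$classes
  rows <- list()
  # returns list(idx in new table, pessimistic error sum)
  walk <- function(i, parent_maj) {
    n0 <- nodes$n_normal[i]; n1 <- nodes$n_tumor[i]
    n <- n0 + n1
    maj <- if (n1 > n0) 2L else if (n0 > n1) 1L else parent_maj
    leaf_row <- function(cls_idx) {
      e <- if (cls_idx == 2L) n0 else n1
      rows[[length(rows) + 1L]] <<- data.frame(
        leaf = TRUE, probe_id = NA_character_, threshold = NA_real_,
        left = NA_integer_, right = NA_integer_, class = classes[cls_idx],
        n_normal = n0, n_tumor = n1, n_covered = n,
        n_misclassified = e, stringsAsFactors = FALSE)
      length(rows)
    }
    if (nodes$leaf[i]) {
      cls_idx <- match(nodes$class[i], classes)
      e <- nodes$n_misclassified[i]
      return(list(idx = leaf_row(cls_idx), est = n * ucf(e, n, confidence)))
    }
    self <- length(rows) + 1L
    rows[[self]] <<- nodes[i, ]
    l <- walk(nodes$left[i], maj)
    r <- walk(nodes$right[i], maj)
    sub <- l$est + r$est
    E <- if (maj == 2L) n0 else n1
    leaf_est <- n * ucf(E, n, confidence)
    if (leaf_est <= sub) {
      rows[(self + 1L):length(rows)] <<- NULL
      rows[[self]] <<- NULL
      return(list(idx = leaf_row(maj), est = leaf_est))
    }
    rows[[self]]$left <<- l$idx
    rows[[self]]$right <<- r$idx
    list(idx = self, est = sub)
  }
  walk(1L, 1L)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  new_c45_tree(out, tree$features, classes, tree$control, tree$n_train,
               call = tree$call)
}

# samples x probes numeric matrix from the accepted newdata forms
newdata_matrix <- function(newdata, needed) {
  if (inherits(newdata, "expression_dataset")) {
    missing <- setdiff(needed, newdata$probe_ids)
    if (length(missing))
      mt_stop(sprintf("newdata lacks probe '%s'", missing[1]),
              "markertree_input_error")
    return(t(newdata$values[needed, , drop = FALSE]))
  }
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1L,
                      dimnames = list(NULL, names(newdata)))
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (!is.matrix(newdata) || is.null(colnames(newdata)))
    mt_stop("newdata must be an expression_dataset, a samples x probes matrix with probe column names, or a named vector",
            "markertree_input_error")
  missing <- setdiff(needed, colnames(newdata))
  if (length(missing))
    mt_stop(sprintf("newdata lacks probe '%s'", missing[1]),
            "markertree_input_error")
  newdata[, needed, drop = FALSE]
}

#' Predict classes with a fitted tree
#'
#' Deterministic root-to-leaf descent: a sample goes left when its value
#' is `<=` the node threshold and right when it is `>`.
#'
#' @param object a `c45_tree`.
#' @param newdata an [expression_dataset], a samples x probes matrix with
#'   probe ids as column names, or a named numeric vector (one sample).
#'   Every probe the tree tests must be present.
#' @param ... unused.
#' @return character vector of predicted classes.
#' @export
predict.c45_tree <- function(object, newdata, ...) {
  nodes <- object$nodes
  used <- unique(nodes$probe_id[!nodes$leaf])
  if (!length(used)) {
    # single-leaf tree tests no probes: constant prediction
    n <- if (inherits(newdata, "expression_dataset")) ncol(newdata$values)
         else if (is.null(dim(newdata))) 1L else nrow(newdata)
    return(rep(nodes$class[1L], n))
  }
  feat_order <- used
  X <- newdata_matrix(newdata, feat_order)
  cls_idx <- match(nodes$class, object$classes) - 1L
  cls_idx[is.na(cls_idx)] <- 0L
  pred <- cpp_predict(nodes$leaf, match(nodes$probe_id, feat_order),
                      nodes$threshold, nodes$left, nodes$right,
                      cls_idx, X)
  out <- object$classes[pred + 1L]
  names(out) <- rownames(X)
  out
}

#' @export
print.c45_tree <- function(x, ...) {
  nodes <- x$nodes
  cat(sprintf("C4.5-style decision tree (%d leaves, %d training samples%s)\n",
              sum(nodes$leaf), x$n_train,
              if (x$control$prune) ", pruned" else ", unpruned"))
  show <- function(i, indent) {
    pad <- strrep("|   ", indent)
    if (nodes$leaf[i]) {
      cat(sprintf(": %s (%d/%d)\n", nodes$class[i], nodes$n_covered[i],
                  nodes$n_misclassified[i]))
    } else {
      cat("\n")
      cat(sprintf("%s%s <= %g", pad, nodes$probe_id[i], nodes$threshold[i]))
      show(nodes$left[i], indent + 1L)
      cat(sprintf("%s%s > %g", pad, nodes$probe_id[i], nodes$threshold[i]))
      show(nodes$right[i], indent + 1L)
    }
  }
  if (nodes$leaf[1L]) {
    cat(sprintf("leaf: %s (%d/%d)\n", nodes$class[1L], nodes$n_covered[1L],
                nodes$n_misclassified[1L]))
  } else show(1L, 0L)
  invisible(x)
}

#' @export
summary.c45_tree <- function(object, ...) {
  nodes <- object$nodes
  leaves <- nodes[nodes$leaf, , drop = FALSE]
  depth <- function(i) {
    if (nodes$leaf[i]) 0L
    else 1L + max(depth(nodes$left[i]), depth(nodes$right[i]))
  }
  out <- list(n_leaves = nrow(leaves), depth = depth(1L),
              n_train = object$n_train,
              training_errors = sum(leaves$n_misclassified),
              training_accuracy = 1 - sum(leaves$n_misclassified) /
                object$n_train,
              probes_used = unique(nodes$probe_id[!nodes$leaf]),
              control = object$control)
  class(out) <- "summary.c45_tree"
  out
}

#' @export
print.summary.c45_tree <- function(x, ...) {
  cat(sprintf("leaves: %d  depth: %d  training accuracy: %.4f (%d/%d errors)\n",
              x$n_leaves, x$depth, x$training_accuracy, x$training_errors,
              x$n_train))
  if (length(x$probes_used))
    cat("probes used:", paste(x$probes_used, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.c45_tree <- function(x, ...) {
  nodes <- x$nodes
  # simple recursive layout: leaves evenly spaced, internal nodes centered
  xs <- numeric(nrow(nodes)); ys <- numeric(nrow(nodes))
  leaf_at <- 0
  place <- function(i, d) {
    ys[i] <<- -d
    if (nodes$leaf[i]) {
      leaf_at <<- leaf_at + 1
      xs[i] <<- leaf_at
    } else {
      place(nodes$left[i], d + 1)
      place(nodes$right[i], d + 1)
      xs[i] <<- (xs[nodes$left[i]] + xs[nodes$right[i]]) / 2
    }
  }
  place(1L, 0)
  plot(xs, ys, type = "n", axes = FALSE, xlab = "", ylab = "",
       ylim = range(ys) + c(-0.5, 0.5), xlim = range(xs) + c(-0.5, 0.5), ...)
  for (i in seq_len(nrow(nodes))) {
    if (!nodes$leaf[i]) {
      for (ch in c(nodes$left[i], nodes$right[i]))
        lines(c(xs[i], xs[ch]), c(ys[i], ys[ch]), col = "grey50")
    }
  }
  lab <- ifelse(nodes$leaf,
                sprintf("%s\n(%d/%d)", nodes$class, nodes$n_covered,
                        nodes$n_misclassified),
                sprintf("%s\n<= %g", nodes$probe_id,
                        signif(nodes$threshold, 5)))
  text(xs, ys, lab, cex = 0.8)
  invisible(x)
}

new_c45_rules <- function(conditions, class, covered, misclassified) {
  structure(list(conditions = conditions, class = class,
                 covered = as.integer(covered),
                 misclassified = as.integer(misclassified)),
            class = "c45_rules")
}

#' Extract the if-then rule set of a fitted tree
#'
#' One rule per leaf: the conjunction of the threshold conditions along the
#' root-to-leaf path, predicting the leaf's class, annotated with the
#' leaf's training coverage and misclassification counts. Because leaves
#' partition the training data, every sample satisfies exactly one rule.
#'
#' @param tree a `c45_tree`.
#' @return An object of class `"c45_rules"`; printing renders each rule as
#'   e.g. `If probe_0042 > 7.523 then tumor (57/4)`.
#' @export
extract_rules <- function(tree) {
  stopifnot(inherits(tree, "c45_tree"))
  nodes <- tree$nodes
  conds <- list(); cls <- character(); cov <- integer(); mis <- integer()
  walk <- function(i, path) {
    if (nodes$leaf[i]) {
      conds[[length(conds) + 1L]] <<- path
      cls <<- c(cls, nodes$class[i])
      cov <<- c(cov, nodes$n_covered[i])
      mis <<- c(mis, nodes$n_misclassified[i])
    } else {
      step <- function(op) data.frame(probe_id = nodes$probe_id[i], op = op,
                                      threshold = nodes$threshold[i],
                                      stringsAsFactors = FALSE)
      walk(nodes$left[i], rbind(path, step("<=")))
      walk(nodes$right[i], rbind(path, step(">")))
    }
  }
  empty <- data.frame(probe_id = character(), op = character(),
                      threshold = numeric(), stringsAsFactors = FALSE)
  walk(1L, empty)
  new_c45_rules(conds, cls, cov, mis)
}

#' @export
print.c45_rules <- function(x, ...) {
  for (i in seq_along(x$class)) {
    cond <- x$conditions[[i]]
    lhs <- if (nrow(cond))
      paste(sprintf("%s %s %g", cond$probe_id, cond$op, cond$threshold),
            collapse = " and ")
    else "TRUE"
    cat(sprintf("If %s then %s (%d/%d)\n", lhs, x$class[i], x$covered[i],
                x$misclassified[i]))
  }
  invisible(x)
}

#' @export
length.c45_rules <- function(x) length(x$class)

#' Predict classes by first-matching-rule evaluation
#'
#' @param object a `c45_rules` set extracted from a tree.
#' @param newdata as in [predict.c45_tree].
#' @param ... unused.
#' @return character vector of predicted classes.
#' @export
predict.c45_rules <- function(object, newdata, ...) {
  needed <- unique(unlist(lapply(object$conditions, function(c) c$probe_id)))
  if (!length(needed))
    needed <- "..none.."
  X <- if (identical(needed, "..none..")) NULL
       else newdata_matrix(newdata, needed)
  n <- if (is.null(X)) {
    if (inherits(newdata, "expression_dataset")) ncol(newdata$values)
    else if (is.null(dim(newdata))) 1L else nrow(newdata)
  } else nrow(X)
  out <- character(n)
  for (s in seq_len(n)) {
    hit <- NA_integer_
    for (r in seq_along(object$class)) {
      cond <- object$conditions[[r]]
      ok <- TRUE
      for (j in seq_len(nrow(cond))) {
        v <- X[s, cond$probe_id[j]]
        ok <- if (cond$op[j] == "<=") v <= cond$threshold[j]
              else v > cond$threshold[j]
        if (!ok) break
      }
      if (ok) { hit <- r; break }
    }
    if (is.na(hit))
      mt_stop("no rule matched the sample (rule set is not a partition)",
              "markertree_input_error")
    out[s] <- object$class[hit]
  }
  out
}
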
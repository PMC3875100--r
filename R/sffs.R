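#' Sequential forward feature selection by cross-validated tree accuracy
#'
#' Greedy wrapper selection: starting from an empty set S, each iteration
#' evaluates the leave-one-out cross-validated accuracy of a decision tree
#' on `S + {p}` for every remaining candidate probe `p` and appends the
#' argmax. Iteration stops once accuracy has not strictly improved for
#' `patience` consecutive iterations (default 2, i.e. two non-improving
#' iterations end the search) or at `max_iter`. The returned `selected`
#' set is the shortest prefix of the chosen sequence attaining the maximum
#' accuracy observed.
#'
#' Accuracy ties between candidates are broken deterministically: first by
#' smaller prefilter adjusted p-value (when `adj_p` is supplied), then by
#' lexicographic probe id. The whole procedure is deterministic — tree
#' induction and LOOCV involve no randomness — so identical inputs yield
#' identical traces.
#'
#' @param ds an [expression_dataset] with both classes present.
#' @param candidates probe ids to select from (e.g. the [prefilter] kept
#'   set, or all probes); must be nonempty.
#' @param control a [c45_control] passed to tree induction.
#' @param patience number of consecutive non-improving iterations after
#'   which the search stops (>= 1).
#' @param max_iter hard cap on iterations.
#' @param adj_p optional named vector of adjusted p-values (probe id ->
#'   adj_p) used for tie-breaking, typically from [prefilter] records.
#' @return An object of class `"sffs_trace"`: `steps` (one row per
#'   iteration: iteration, n_candidates_evaluated, chosen_probe,
#'   loocv_accuracy_after, improved) and `selected` (the final biomarker
#'   probe set, a prefix of the chosen sequence).
#' @seealso [loocv], [c45]
#' @export
sffs <- function(ds, candidates = NULL, control = c45_control(),
                 patience = 2L, max_iter = 10L, adj_p = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  assert_two_class(ds)
  candidates <- candidates %||% ds$probe_ids
  if (!length(candidates))
    mt_stop("'candidates' must name at least one probe",
            "markertree_usage_error")
  unknown <- setdiff(candidates, ds$probe_ids)
  if (length(unknown))
    mt_stop(sprintf("unknown candidate probe '%s'", unknown[1]),
            "markertree_usage_error")
  patience <- as.integer(patience)
  max_iter <- as.integer(max_iter)
  if (is.na(patience) || patience < 1L || is.na(max_iter) || max_iter < 1L)
    mt_stop("'patience' and 'max_iter' must be >= 1", "markertree_usage_error")

  Xt <- t(ds$values[ds$probe_ids, , drop = FALSE])
  colnames(Xt) <- ds$probe_ids
  y <- as.integer(ds$labels == "tumor")
  n <- length(y)
  tie_p <- function(p) {
    if (is.null(adj_p)) return(rep(Inf, length(p)))
    v <- unname(adj_p[p])
    v[is.na(v)] <- Inf
    v
  }

  chosen <- character()
  remaining <- candidates
  best_acc <- -Inf
  stall <- 0L
  steps <- vector("list", max_iter)
  it <- 0L
  while (it < max_iter && stall < patience && length(remaining)) {
    it <- it + 1L
    acc <- vapply(remaining, function(p) {
      pred <- cpp_loocv(Xt[, c(chosen, p), drop = FALSE], y,
                        control$min_leaf,
                        control$criterion == "gain_ratio", control$mdl,
                        control$prune, control$confidence)
      mean(pred == y)
    }, 0)
    ord <- order(-acc, tie_p(remaining), remaining)
    pick <- remaining[ord[1L]]
    pick_acc <- unname(acc[ord[1L]])
    improved <- pick_acc > best_acc
    if (improved) {
      best_acc <- pick_acc
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    steps[[it]] <- data.frame(iteration = it,
                              n_candidates_evaluated = length(remaining),
                              chosen_probe = pick,
                              loocv_accuracy_after = pick_acc,
                              improved = improved,
                              stringsAsFactors = FALSE)
    chosen <- c(chosen, pick)
    remaining <- setdiff(remaining, pick)
  }
  steps <- do.call(rbind, steps[seq_len(it)])
  rownames(steps) <- NULL
  best_prefix <- which(steps$loocv_accuracy_after ==
                         max(steps$loocv_accuracy_after))[1L]
  structure(list(steps = steps, selected = chosen[seq_len(best_prefix)],
                 patience = patience, max_iter = max_iter,
                 control = control),
            class = "sffs_trace")
}

#' @export
print.sffs_trace <- function(x, ...) {
  cat(sprintf("sequential forward selection: %d iteration(s), %d probe(s) selected\n",
              nrow(x$steps), length(x$selected)))
  for (i in seq_len(nrow(x$steps))) {
    s <- x$steps[i, ]
    cat(sprintf("  iter %d: chose %s, LOOCV accuracy %.4f%s (%d candidates)\n",
                s$iteration, s$chosen_probe, s$loocv_accuracy_after,
                if (s$improved) " *" else "", s$n_candidates_evaluated))
  }
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.sffs_trace <- function(x, ...) {
  s <- x$steps
  plot(s$iteration, s$loocv_accuracy_after, type = "b", pch = 19,
       xlab = "iteration", ylab = "LOOCV accuracy",
       ylim = c(min(s$loocv_accuracy_after) - 0.02, 1), xaxt = "n", ...)
  axis(1, at = s$iteration, labels = s$chosen_probe, las = 2, cex.axis = 0.7)
  points(s$iteration[!s$improved], s$loocv_accuracy_after[!s$improved],
         pch = 1)
  invisible(x)
}
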
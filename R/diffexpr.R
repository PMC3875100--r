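#' Two-sample t-test on one probe
#'
#' Ordinary (not moderated) two-sample t-test of tumor versus normal
#' log2 intensities. The sign convention is positive when `mean(x) >
#' mean(y)` with `x` the tumor group. The degenerate case of zero variance
#' in both groups with equal means is defined as `t = 0, p = 1`; with
#' different means the statistic is infinite and `p = 0`.
#'
#' @param x numeric vector, tumor group (length >= 2).
#' @param y numeric vector, normal group (length >= 2).
#' @param variant `"pooled"` (Student, equal variances; default) or
#'   `"welch"`.
#' @param paired paired test (requires equal lengths, samples matched by
#'   position).
#' @return `list(t_stat, df, p_value)` with a two-sided p-value.
#' @examples
#' two_sample_t(c(4, 5, 6), c(1, 2, 3))  # t = 3.6742, df = 4
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch"),
                         paired = FALSE) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L)
    mt_stop("each group needs at least 2 observations",
            "markertree_insufficient_data_error")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    mt_stop("inputs must be finite", "markertree_domain_error")
  if (paired && length(x) != length(y))
    mt_stop("paired test requires equal group sizes",
            "markertree_insufficient_data_error")
  if (paired) {
    d <- x - y
    if (sd(d) == 0) {
      df <- length(d) - 1
      if (mean(d) == 0) return(list(t_stat = 0, df = df, p_value = 1))
      return(list(t_stat = sign(mean(d)) * Inf, df = df, p_value = 0))
    }
    tt <- t.test(x, y, paired = TRUE)
    return(list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value))
  }
  if (sd(x) == 0 && sd(y) == 0) {
    df <- length(x) + length(y) - 2
    if (mean(x) == mean(y)) return(list(t_stat = 0, df = df, p_value = 1))
    return(list(t_stat = sign(mean(x) - mean(y)) * Inf, df = df,
                p_value = 0))
  }
  tt <- t.test(x, y, var.equal = (variant == "pooled"))
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values: with p-values ranked ascending,
#' `adj_(i) = min over j with rank(j) >= rank(i) of min(1, p_(j) * n /
#' rank(j))`, returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.04 0.04
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    mt_stop("p-values must lie in [0, 1]", "markertree_domain_error")
  p.adjust(p, method = "BH")
}

#' Differential-expression prefilter
#'
#' Per-probe two-sample t-tests (tumor vs normal) with Benjamini-Hochberg
#' correction, keeping probes that are both significant at `adj_p < alpha`
#' (strict) and overexpressed in tumor (`mean_tumor > mean_normal`).
#' Records are returned for every probe regardless of the filter, and the
#' kept set preserves the input probe order.
#'
#' Note: this is an ordinary t-test, not an empirical-Bayes moderated
#' statistic, so kept-set sizes are not comparable to pipelines that use
#' variance moderation; the choice is recorded in the result.
#'
#' @param ds an [expression_dataset] with both classes present.
#' @param alpha significance threshold on the adjusted p-value, in (0, 1].
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @param paired paired per-probe tests (requires equally sized classes,
#'   pairs matched by within-class order).
#' @return An object of class `"diffexpr"`: `records` (one row per probe:
#'   probe_id, mean_tumor, mean_normal, t_stat, df, p_value, adj_p,
#'   overexpressed) and `kept` (probe ids passing the filter).
#' @export
prefilter <- function(ds, alpha = 0.001, variant = c("pooled", "welch"),
                      paired = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  variant <- match.arg(variant)
  assert_two_class(ds)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    mt_stop("'alpha' must lie in (0, 1]", "markertree_domain_error")
  tum <- ds$labels == "tumor"
  X <- ds$values[, tum, drop = FALSE]
  Y <- ds$values[, !tum, drop = FALSE]
  mean_tumor <- rowMeans(X)
  mean_normal <- rowMeans(Y)
  tests <- lapply(seq_len(nrow(ds$values)), function(i)
    two_sample_t(X[i, ], Y[i, ], variant = variant, paired = paired))
  t_stat <- vapply(tests, `[[`, 0, "t_stat")
  dfree <- vapply(tests, `[[`, 0, "df")
  p_value <- vapply(tests, `[[`, 0, "p_value")
  adj_p <- bh_adjust(p_value)
  over <- mean_tumor > mean_normal
  records <- data.frame(probe_id = ds$probe_ids, mean_tumor = mean_tumor,
                        mean_normal = mean_normal, t_stat = t_stat,
                        df = dfree, p_value = p_value, adj_p = adj_p,
                        overexpressed = over, row.names = NULL,
                        stringsAsFactors = FALSE)
  kept <- ds$probe_ids[adj_p < alpha & over]
  structure(list(records = records, kept = kept, alpha = alpha,
                 variant = variant, paired = paired),
            class = "diffexpr")
}

#' @export
print.diffexpr <- function(x, ...) {
  cat(sprintf("differential expression: %d probes tested (%s t-test%s), %d kept at adj_p < %g and overexpressed in tumor\n",
              nrow(x$records), x$variant,
              if (isTRUE(x$paired)) ", paired" else "", length(x$kept),
              x$alpha))
  cat("note: ordinary t statistics (no empirical-Bayes moderation)\n")
  invisible(x)
}
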
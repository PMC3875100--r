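#' Present/Absent detection call for array spots
#'
#' A spot is called Present when its foreground median intensity is at
#' least the background median plus three background standard deviations:
#' `fg_median >= bg_median + 3 * bg_sd`.
#'
#' @param fg_median foreground median intensity (>= 0), or a data frame of
#'   spot statistics with columns `fg_median`, `bg_median`, `bg_sd`.
#' @param bg_median background median intensity (>= 0).
#' @param bg_sd background standard deviation (>= 0).
#' @return logical vector of Present calls.
#' @examples
#' present_flag(100, 70, 10)   # TRUE (boundary: 70 + 3*10 = 100)
#' present_flag(99.9, 70, 10)  # FALSE
#' @export
present_flag <- function(fg_median, bg_median = NULL, bg_sd = NULL) {
  if (is.data.frame(fg_median)) {
    spots <- fg_median
    fg_median <- spots$fg_median
    bg_median <- spots$bg_median
    bg_sd <- spots$bg_sd
  }
  if (any(fg_median < 0) || any(bg_median < 0) || any(bg_sd < 0))
    mt_stop("spot intensities and background sd must be nonnegative",
            "markertree_domain_error")
  fg_median >= bg_median + 3 * bg_sd
}

#' Read a spot-statistics table
#'
#' One file per array: tab-delimited with columns `spot_id`, `fg_median`,
#' `bg_median`, `bg_sd` and optionally a logical `is_control` marking
#' control spots (needed for the control-CV quality parameter).
#'
#' @param path path to the TSV file.
#' @return data frame of spot statistics.
#' @export
read_spot_stats <- function(path) {
  if (!file.exists(path))
    mt_stop(sprintf("file not found: %s", path), "markertree_format_error")
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("spot_id", "fg_median", "bg_median", "bg_sd")
  missing <- setdiff(need, colnames(tab))
  if (length(missing))
    mt_stop(sprintf("spot table lacks column '%s'", missing[1]),
            "markertree_format_error")
  if ("is_control" %in% colnames(tab))
    tab$is_control <- as.logical(tab$is_control)
  else tab$is_control <- FALSE
  if (any(tab$fg_median < 0) || any(tab$bg_median < 0) || any(tab$bg_sd < 0))
    mt_stop("spot intensities and background sd must be nonnegative",
            "markertree_domain_error")
  tab
}

#' Per-array quality summary
#'
#' The three array-level quality parameters used by [basic_qc]: the
#' percentage of Present spots among all spots, the average intensity of
#' Present spots, and the coefficient of variation of control-spot
#' intensities. Intensities are the raw foreground medians (the choice is
#' recorded in the report).
#'
#' @param spots a spot-statistics data frame (see [read_spot_stats]).
#' @param array_id identifier for the array.
#' @return one-row data frame of class `"array_qc_report"` with columns
#'   `array_id`, `pct_present`, `mean_present_intensity`, `control_cv`.
#' @export
array_qc_report <- function(spots, array_id) {
  pres <- present_flag(spots)
  ctrl <- spots$fg_median[spots$is_control]
  out <- data.frame(array_id = as.character(array_id),
                    pct_present = 100 * mean(pres),
                    mean_present_intensity =
                      if (any(pres)) mean(spots$fg_median[pres]) else NA_real_,
                    control_cv =
                      if (length(ctrl) >= 2 && mean(ctrl) > 0)
                        sd(ctrl) / mean(ctrl) else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "intensity") <- "raw fg_median"
  class(out) <- c("array_qc_report", "data.frame")
  out
}

#' Basic array-level quality filter
#'
#' For each of the three quality parameters (`pct_present`,
#' `mean_present_intensity`, `control_cv`) the acceptance interval
#' `[Q1 - 1.5*IQR, Q3 + 1.5*IQR]` is computed across all arrays (quartiles
#' by linear interpolation, `stats::quantile` type 7). An array fails —
#' `basic_pass = FALSE` — when two or more of its parameters fall outside
#' their intervals; a single outlying parameter is tolerated.
#'
#' @param reports data frame of per-array reports (rows from
#'   [array_qc_report]); at least 4 arrays so quartiles are meaningful.
#' @return the reports with `basic_pass` (logical) and `outlier_params`
#'   (list column naming the out-of-range parameters) filled in.
#' @export
basic_qc <- function(reports) {
  reports <- as.data.frame(reports)
  if (nrow(reports) < 4L)
    mt_stop("basic QC needs at least 4 arrays for meaningful quartiles",
            "markertree_insufficient_data_error")
  params <- c("pct_present", "mean_present_intensity", "control_cv")
  outside <- matrix(FALSE, nrow(reports), length(params),
                    dimnames = list(NULL, params))
  for (p in params) {
    v <- reports[[p]]
    q <- quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[2] + 1.5 * iqr
    outside[, p] <- !is.na(v) & (v < lo | v > hi)
  }
  reports$outlier_params <- apply(outside, 1L, function(r)
    params[r], simplify = FALSE)
  reports$basic_pass <- rowSums(outside) < 2L
  reports
}

#' Replicate-array reproducibility check
#'
#' Repeated arrays of the same sample pass when their Pearson correlation
#' exceeds 0.95 and the "2-fold percentage" — the percentage of probes
#' whose raw-scale intensity ratio between the two arrays exceeds 2-fold
#' in either direction (ratio > 2 or < 1/2) — is below 15%. Both
#' inequalities are strict.
#'
#' @param a,b raw-scale intensity vectors of the same probes on the two
#'   arrays (equal length >= 3, strictly positive).
#' @return `list(pearson_r, two_fold_pct, pass)`.
#' @export
reproducibility_check <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    mt_stop("replicate vectors must have equal length >= 3",
            "markertree_insufficient_data_error")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    mt_stop("intensities must be finite", "markertree_domain_error")
  if (any(a <= 0) || any(b <= 0))
    mt_stop("raw-scale intensities must be strictly positive",
            "markertree_domain_error")
  if (sd(a) == 0 || sd(b) == 0)
    mt_stop("correlation is undefined for a zero-variance array",
            "markertree_domain_error")
  r <- cor(a, b)
  ratio <- a / b
  pct <- 100 * mean(ratio > 2 | ratio < 0.5)
  list(pearson_r = r, two_fold_pct = pct, pass = (r > 0.95) && (pct < 15))
}

#' Union of Present calls across qualified arrays
#'
#' A probe is retained for analysis when it is Present on at least one
#' qualified array (elementwise OR of the per-array masks).
#'
#' @param masks logical matrix (probes x arrays) or list of equally named
#'   logical vectors sharing one probe universe.
#' @return logical inclusion mask over probes.
#' @export
present_union_filter <- function(masks) {
  if (is.list(masks) && !is.data.frame(masks)) {
    universes <- lapply(masks, names)
    ref <- universes[[1]]
    same <- vapply(universes, identical, TRUE, y = ref)
    if (is.null(ref) || !all(same))
      mt_stop("per-array Present masks must share one named probe universe",
              "markertree_alignment_error")
    masks <- do.call(cbind, masks)
  }
  if (!is.logical(masks))
    mt_stop("masks must be logical", "markertree_alignment_error")
  rowSums(masks, na.rm = TRUE) > 0
}

#' Per-array intensity histogram table
#'
#' Exports the binned distribution of spot foreground intensities so the
#' density-profile ("diagram") inspection of replicate arrays can be done
#' visually; no automated pass/fail is applied because the comparison has
#' no quantitative criterion.
#'
#' @param spots spot-statistics data frame.
#' @param bins number of equal-width bins.
#' @return data frame with `bin_low`, `bin_high`, `count`.
#' @export
intensity_histogram <- function(spots, bins = 50L) {
  v <- spots$fg_median
  br <- seq(min(v), max(v), length.out = bins + 1L)
  if (br[1] == br[length(br)]) br <- c(br[1] - 0.5, br[1] + 0.5)
  h <- hist(v, breaks = br, plot = FALSE)
  data.frame(bin_low = h$breaks[-length(h$breaks)],
             bin_high = h$breaks[-1], count = h$counts)
}
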
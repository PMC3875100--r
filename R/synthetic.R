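#' Specify a synthetic two-class expression dataset
#'
#' Describes a probes x samples log2-intensity matrix with known ground
#' truth: iid Gaussian background probes plus planted markers. Roles:
#' `single_marker` (shifted `+delta*sigma` in every tumor sample),
#' `down_marker` (shifted `-delta*sigma` in every tumor sample, the
#' down-in-tumor direction), and the complementary pair `pair_A` /
#' `pair_B`: A is shifted in a seeded random tumor subset of size
#' `round(f * n_tumor)` and B in the complementary subset, so neither gene
#' alone separates all tumors from normals but together they support a
#' perfectly separating depth-2 tree. Pair roles are matched in order of
#' appearance (first A with first B) and must come in equal numbers.
#'
#' Defaults encode the package's reference scenario: 30 tumor / 30 normal
#' samples, 500 probes, one complementary pair at `delta = 2` background
#' standard deviations with `f = 0.9`, background `Normal(8, 1)` on the
#' log2 scale.
#'
#' @param n_tumor,n_normal samples per class.
#' @param n_probes total probes (>= number of planted probes).
#' @param planted data frame with columns `role`, `delta` (effect in
#'   background-sd units) and `f` (coverage fraction in (0,1) for pair
#'   roles, ignored otherwise).
#' @param mu_bg,sigma_bg background log2-intensity mean and sd
#'   (`sigma_bg > 0`).
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_tumor = 30L, n_normal = 30L, n_probes = 500L,
                           planted = data.frame(
                             role = c("pair_A", "pair_B"),
                             delta = 2, f = 0.9,
                             stringsAsFactors = FALSE),
                           mu_bg = 8, sigma_bg = 1, seed = 1L) {
  n_tumor <- as.integer(n_tumor); n_normal <- as.integer(n_normal)
  n_probes <- as.integer(n_probes)
  if (is.na(n_tumor) || n_tumor < 1L || is.na(n_normal) || n_normal < 1L)
    mt_stop("sample counts must be positive", "markertree_validation_error")
  if (!is.data.frame(planted))
    planted <- as.data.frame(planted, stringsAsFactors = FALSE)
  if (nrow(planted)) {
    planted$role <- as.character(planted$role)
    planted$delta <- as.numeric(rep_len(planted$delta, nrow(planted)))
    planted$f <- if (is.null(planted[["f"]])) NA_real_
                 else as.numeric(rep_len(planted$f, nrow(planted)))
    bad <- setdiff(planted$role,
                   c("single_marker", "down_marker", "pair_A", "pair_B"))
    if (length(bad))
      mt_stop(sprintf("unknown planted role '%s'", bad[1]),
              "markertree_validation_error")
    if (sum(planted$role == "pair_A") != sum(planted$role == "pair_B"))
      mt_stop("pair_A and pair_B roles must come in equal numbers",
              "markertree_validation_error")
    pairf <- planted$f[planted$role %in% c("pair_A", "pair_B")]
    if (any(is.na(pairf)) || any(pairf <= 0) || any(pairf >= 1))
      mt_stop("pair coverage fraction 'f' must lie strictly between 0 and 1",
              "markertree_validation_error")
    if (any(!is.finite(planted$delta)))
      mt_stop("planted effect 'delta' must be finite",
              "markertree_validation_error")
  }
  if (is.na(n_probes) || n_probes < nrow(planted))
    mt_stop("'n_probes' must be at least the number of planted probes",
            "markertree_validation_error")
  if (!is.finite(sigma_bg) || sigma_bg <= 0)
    mt_stop("'sigma_bg' must be positive", "markertree_validation_error")
  structure(list(n_tumor = n_tumor, n_normal = n_normal,
                 n_probes = n_probes, planted = planted, mu_bg = mu_bg,
                 sigma_bg = sigma_bg, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Draws the background matrix iid `Normal(mu_bg, sigma_bg)` for both
#' classes, assigns planted probes to seeded random rows, and applies the
#' role-specific tumor shifts described in [synthetic_spec]. The result is
#' byte-identical for the same seed.
#'
#' @param spec a [synthetic_spec].
#' @return `list(dataset, truth)`: the [expression_dataset], and a `truth`
#'   list with `planted` (data frame: probe_id, role, delta, f),
#'   `shifted_samples` (per planted probe, the tumor sample ids that
#'   received the shift) and `column_means` (bookkeeping of the generated
#'   matrix's per-sample means).
#' @examples
#' sim <- simulate_expression(synthetic_spec(seed = 42))
#' sim$dataset
#' sim$truth$planted
#' @export
simulate_expression <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    mt_stop("'spec' must be a synthetic_spec", "markertree_validation_error")
  n <- spec$n_tumor + spec$n_normal
  sample_ids <- c(sprintf("tumor_%02d", seq_len(spec$n_tumor)),
                  sprintf("normal_%02d", seq_len(spec$n_normal)))
  labels <- rep(c("tumor", "normal"), c(spec$n_tumor, spec$n_normal))
  probe_ids <- sprintf("probe_%05d", seq_len(spec$n_probes))
  planted <- spec$planted
  truth_rows <- NULL
  shifted <- list()
  values <- with_seed(spec$seed, {
    m <- matrix(rnorm(spec$n_probes * n, spec$mu_bg, spec$sigma_bg),
                nrow = spec$n_probes, ncol = n,
                dimnames = list(probe_ids, sample_ids))
    if (nrow(planted)) {
      rows <- sample(spec$n_probes, nrow(planted))
      truth_rows <- data.frame(probe_id = probe_ids[rows],
                               role = planted$role, delta = planted$delta,
                               f = planted$f, stringsAsFactors = FALSE)
      tumor_cols <- seq_len(spec$n_tumor)
      a_idx <- which(planted$role == "pair_A")
      b_idx <- which(planted$role == "pair_B")
      pair_subsets <- lapply(seq_along(a_idx), function(j) {
        size <- round(planted$f[a_idx[j]] * spec$n_tumor)
        sort(sample(tumor_cols, size))
      })
      for (j in seq_len(nrow(planted))) {
        shift <- planted$delta[j] * spec$sigma_bg
        cols <- switch(planted$role[j],
          single_marker = tumor_cols,
          down_marker = tumor_cols,
          pair_A = pair_subsets[[match(j, a_idx)]],
          pair_B = setdiff(tumor_cols, pair_subsets[[match(j, b_idx)]]))
        if (planted$role[j] == "down_marker") shift <- -shift
        m[rows[j], cols] <- m[rows[j], cols] + shift
        shifted[[probe_ids[rows[j]]]] <- sample_ids[cols]
      }
    }
    m
  })
  ds <- expression_dataset(values, labels, probe_ids = probe_ids,
                           sample_ids = sample_ids,
                           meta = list(generator = "markertree synthetic",
                                       seed = spec$seed))
  truth <- list(planted = truth_rows %||%
                  data.frame(probe_id = character(), role = character(),
                             delta = numeric(), f = numeric(),
                             stringsAsFactors = FALSE),
                shifted_samples = shifted,
                column_means = colMeans(values),
                spec = spec)
  list(dataset = ds, truth = truth)
}
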
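# Fixture builders and independent oracles shared across the test files.
# Oracles are deliberately naive (enumeration / direct formulas) and never
# call the code paths they check.

make_ds <- function(values, labels) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_dataset(values, labels)
}

# two-feature interaction fixture: tumor iff A > 5 or B > 5 (the
# complementary-pair motif), four well separated clusters
pair_motif_ds <- function() {
  a <- c(rep(8, 5), rep(2, 5), rep(8, 5), rep(2, 10)) +
    seq(0, 0.4, length.out = 25)
  b <- c(rep(2, 5), rep(8, 5), rep(8, 5), rep(2, 10)) +
    seq(0, 0.4, length.out = 25)
  labels <- rep(c("tumor", "normal"), c(15, 10))
  make_ds(rbind(A = a, B = b), labels)
}

drop_sample <- function(ds, i) {
  expression_dataset(ds$values[, -i, drop = FALSE], ds$labels[-i])
}

one_sample <- function(ds, i) {
  expression_dataset(ds$values[, i, drop = FALSE], ds$labels[i])
}

random_fixture <- function(n_samples = 8, n_features = 5, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n_features * n_samples), n_features, n_samples)
  labels <- sample(c("tumor", "normal"), n_samples, replace = TRUE)
  # guarantee both classes
  labels[1] <- "tumor"; labels[2] <- "normal"
  make_ds(vals, labels)
}

entropy_oracle <- function(c0, c1) {
  n <- c0 + c1
  h <- 0
  for (c in c(c0, c1)) if (c > 0) h <- h - (c / n) * log2(c / n)
  h
}

# exhaustive enumeration over every observed threshold
oracle_best_split <- function(v, y, min_leaf = 1, criterion = "info_gain",
                              mdl = FALSE) {
  n <- length(v)
  parent <- entropy_oracle(sum(y == 0), sum(y == 1))
  cand <- sort(unique(v))
  cand <- cand[-length(cand)]
  adm <- Filter(function(t) {
    nl <- sum(v <= t)
    nl >= min_leaf && (n - nl) >= min_leaf
  }, cand)
  if (!length(adm)) return(NULL)
  penalty <- if (mdl) log2(length(adm)) / n else 0
  scores <- vapply(adm, function(t) {
    l <- y[v <= t]; r <- y[v > t]
    gain <- parent -
      (length(l) * entropy_oracle(sum(l == 0), sum(l == 1)) +
       length(r) * entropy_oracle(sum(r == 0), sum(r == 1))) / n -
      penalty
    if (criterion == "gain_ratio") {
      si <- entropy_oracle(length(l), length(r))
      if (si <= 0) return(-Inf)
      gain / si
    } else gain
  }, 0)
  if (max(scores) <= 1e-12) return(NULL)
  list(threshold = adm[which.max(scores)], score = max(scores),
       all = data.frame(threshold = adm, score = scores))
}

# step-up definition applied literally
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  for (pos in seq_len(n)) {
    candidates <- vapply(pos:n, function(q) min(1, p[ord[q]] * n / q), 0)
    adj[ord[pos]] <- min(candidates)
  }
  adj
}

# bisection on the binomial tail for the pruning bound
oracle_ucf <- function(e, n, cf, tol = 1e-12) {
  if (e >= n) return(1)
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pbinom(e, n, mid) > cf) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

training_accuracy <- function(tree) {
  leaves <- tree$nodes[tree$nodes$leaf, ]
  1 - sum(leaves$n_misclassified) / tree$n_train
}
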
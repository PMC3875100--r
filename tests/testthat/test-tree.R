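test_that("entropy matches the formula on the worked cases", {
  expect_equal(entropy(c(5, 5)), 1.0)
  expect_equal(entropy(c(10, 0)), 0.0)
  expect_equal(entropy(c(2, 6)), 0.8113, tolerance = 1e-4)
  expect_equal(entropy(c(2, 6)), entropy_oracle(2, 6))
  expect_error(entropy(c(0, 0)), class = "markertree_domain_error")
})

test_that("best_split finds the optimal observed threshold", {
  s <- best_split(c(1, 2, 3, 4), c("N", "N", "T", "T"))
  expect_equal(s$threshold, 2)
  expect_equal(s$score, 1.0)  # perfect split: gain equals parent entropy
  expect_null(best_split(rep(2, 6), rep(c("N", "T"), 3)))

  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(4:50, 1)
    v <- sample(round(rnorm(n), 2), n, replace = TRUE)  # induce ties
    y <- sample(0:1, n, replace = TRUE)
    for (crit in c("info_gain", "gain_ratio")) {
      for (mdl in c(FALSE, TRUE)) {
        got <- best_split(v, y, criterion = crit, mdl = mdl)
        want <- oracle_best_split(v, y, criterion = crit, mdl = mdl)
        if (is.null(want)) {
          expect_null(got)
        } else {
          expect_equal(got$score, want$score, tolerance = 1e-9)
          # the returned threshold must attain the oracle maximum
          at <- want$all$score[want$all$threshold == got$threshold]
          expect_equal(at, want$score, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("growth stops at purity and solves the two-gene interaction at depth 2", {
  pure <- make_ds(matrix(rnorm(20, 8), 2, 10), rep("tumor", 10))
  fit <- c45(pure)
  expect_equal(nrow(fit$nodes), 1L)
  expect_identical(fit$nodes$class[1], "tumor")
  expect_equal(fit$nodes$n_misclassified[1], 0L)

  # complementary-pair motif: tumor iff A high or B high
  fit2 <- c45(pair_motif_ds())
  expect_equal(summary(fit2)$depth, 2L)
  expect_equal(training_accuracy(fit2), 1.0)
  expect_error(c45(pair_motif_ds(), features = character()),
               class = "markertree_usage_error")
})

test_that("conflict-free fixtures are fit perfectly by unpruned trees", {
  ctl <- c45_control(min_leaf = 1, mdl = FALSE, prune = FALSE)
  for (seed in 1:20) {
    ds <- random_fixture(n_samples = sample(4:10, 1),
                         n_features = sample(1:5, 1), seed = seed)
    fit <- c45(ds, control = ctl)
    expect_equal(training_accuracy(fit), 1.0)
    expect_identical(unname(predict(fit, ds)), ds$labels)
    # leaves partition the training samples
    expect_equal(sum(fit$nodes$n_covered[fit$nodes$leaf]), ncol(ds$values))
  }
})

test_that("the pruning bound matches the closed form and a bisection oracle", {
  expect_equal(ucf(0, 2, 0.25), 0.5)
  expect_equal(ucf(0, 51, 0.25), 1 - 0.25^(1 / 51))
  expect_equal(ucf(0, 51, 0.25), 0.02682, tolerance = 1e-3)
  for (n in c(1, 2, 5, 20, 51)) {
    expect_equal(ucf(0, n, 0.25), 1 - 0.25^(1 / n), tolerance = 1e-12)
  }
  expect_equal(ucf(2, 20, 0.25), oracle_ucf(2, 20, 0.25), tolerance = 1e-9)
  for (case in list(c(1, 4), c(3, 10), c(7, 31), c(10, 10))) {
    expect_equal(ucf(case[1], case[2], 0.25),
                 oracle_ucf(case[1], case[2], 0.25), tolerance = 1e-9)
  }
  expect_error(ucf(5, 4), class = "markertree_domain_error")
})

test_that("subtree replacement follows the pessimistic-error inequality", {
  # hand-built root with two one-sample leaves, CF = 0.25:
  # leaves' estimate = 2 * 1 * ucf(0,1) = 1.5
  mk <- function(left_class, right_class) {
    nodes <- data.frame(
      leaf = c(FALSE, TRUE, TRUE), probe_id = c("g", NA, NA),
      threshold = c(5, NA, NA), left = c(2L, NA, NA),
      right = c(3L, NA, NA), class = c(NA, left_class, right_class),
      n_normal = c(sum(c(left_class, right_class) == "normal"),
                   as.integer(left_class == "normal"),
                   as.integer(right_class == "normal")),
      n_tumor = c(sum(c(left_class, right_class) == "tumor"),
                  as.integer(left_class == "tumor"),
                  as.integer(right_class == "tumor")),
      stringsAsFactors = FALSE)
    nodes$n_covered <- nodes$n_normal + nodes$n_tumor
    nodes$n_misclassified <- ifelse(nodes$leaf, 0L, NA_integer_)
    markertree:::new_c45_tree(nodes, features = "g",
                              classes = c("normal", "tumor"),
                              control = c45_control(), n_train = 2L)
  }
  # same-class leaves: merged leaf has 0 errors, 2*ucf(0,2) = 1 <= 1.5 -> prune
  pruned <- prune_tree(mk("tumor", "tumor"))
  expect_equal(nrow(pruned$nodes), 1L)
  expect_identical(pruned$nodes$class[1], "tumor")
  # different classes: merged leaf has 1 error, 2*ucf(1,2) ~ 1.732 > 1.5 -> keep
  kept <- prune_tree(mk("normal", "tumor"))
  expect_equal(sum(kept$nodes$leaf), 2L)

  # a clean informative split survives pruning
  ds <- make_ds(matrix(c(1, 2, 3, 10, 11, 12), 1), rep(c("normal", "tumor"),
                                                       each = 3))
  fit <- c45(ds, control = c45_control(min_leaf = 1))
  expect_equal(sum(fit$nodes$leaf), 2L)
})

test_that("R and C++ pruners agree; pruning never grows the tree", {
  for (seed in 1:100) {
    ds <- random_fixture(n_samples = sample(6:14, 1),
                         n_features = sample(1:4, 1), seed = seed + 500)
    grown <- c45(ds, control = c45_control(min_leaf = 1, mdl = FALSE,
                                           prune = FALSE))
    via_r <- prune_tree(grown)
    via_cpp <- c45(ds, control = c45_control(min_leaf = 1, mdl = FALSE,
                                             prune = TRUE))
    expect_equal(via_r$nodes[names(via_r$nodes) != "probe_id"],
                 via_cpp$nodes[names(via_cpp$nodes) != "probe_id"])
    expect_identical(via_r$nodes$probe_id, via_cpp$nodes$probe_id)
    expect_lte(sum(via_r$nodes$leaf), sum(grown$nodes$leaf))
    expect_lte(training_accuracy(via_r), training_accuracy(grown))
  }
})

test_that("prediction descends <= left, > right, with the printed boundary", {
  ds <- make_ds(matrix(c(7.0, 7.2, 7.523, 8.0, 8.1, 9.0), 1,
                       dimnames = list("RUVBL1", NULL)),
                rep(c("normal", "tumor"), each = 3))
  fit <- c45(ds)
  expect_equal(fit$nodes$threshold[1], 7.523)
  expect_identical(unname(predict(fit, c(RUVBL1 = 8.0))), "tumor")
  expect_identical(unname(predict(fit, c(RUVBL1 = 7.523))), "normal")
  expect_error(predict(fit, c(OTHER = 8.0)), class = "markertree_input_error")
})

test_that("one rule per leaf; rules partition samples and reproduce predictions", {
  fit <- c45(pair_motif_ds())
  rules <- extract_rules(fit)
  expect_length(rules, sum(fit$nodes$leaf))
  expect_equal(sum(rules$covered), fit$n_train)

  # every training sample satisfies exactly one rule
  X <- t(pair_motif_ds()$values)
  for (s in seq_len(nrow(X))) {
    hits <- vapply(seq_along(rules$class), function(r) {
      cond <- rules$conditions[[r]]
      all(vapply(seq_len(nrow(cond)), function(j) {
        v <- X[s, cond$probe_id[j]]
        if (cond$op[j] == "<=") v <= cond$threshold[j] else v > cond$threshold[j]
      }, TRUE))
    }, TRUE)
    expect_equal(sum(hits), 1L)
  }

  # tree and first-matching-rule evaluation agree on arbitrary inputs
  set.seed(2)
  newx <- matrix(runif(200, 0, 10), 100, 2,
                 dimnames = list(NULL, c("A", "B")))
  expect_identical(predict(rules, newx), unname(predict(fit, newx)))

  single <- extract_rules(c45(make_ds(matrix(rnorm(10), 1, 10),
                                      rep("normal", 10))))
  expect_length(single, 1L)
  expect_equal(nrow(single$conditions[[1]]), 0L)
})
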
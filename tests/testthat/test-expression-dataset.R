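test_that("constructor enforces shape, id uniqueness, finiteness and labels", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
  ds <- expression_dataset(m, c("tumor", "normal", "normal"))
  expect_s3_class(ds, "expression_dataset")
  expect_equal(dim(ds), c(2L, 3L))

  expect_error(expression_dataset(m, c("tumor", "normal")),
               class = "markertree_label_error")
  expect_error(expression_dataset(m, c("tumor", "normal", "case")),
               class = "markertree_label_error")
  m2 <- m; rownames(m2) <- c("p1", "p1")
  expect_error(expression_dataset(m2, c("tumor", "normal", "normal")),
               class = "markertree_format_error")
  m3 <- m; m3[1, 1] <- NA
  expect_error(expression_dataset(m3, c("tumor", "normal", "normal")),
               class = "markertree_format_error")
})

test_that("expression TSV round-trips identically", {
  m <- matrix(c(1.25, -2.5, 3.75, 4.125), 2, 2,
              dimnames = list(c("pA", "pB"), c("s1", "s2")))
  ds <- expression_dataset(m, c("tumor", "normal"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(ds, path)
  back <- read_expression_tsv(path, c(s1 = "tumor", s2 = "normal"))
  expect_identical(back$probe_ids, ds$probe_ids)
  expect_identical(back$sample_ids, ds$sample_ids)
  expect_identical(back$labels, ds$labels)
  expect_equal(back$values, ds$values, tolerance = 1e-12)
})

test_that("reading a generated dataset reproduces the generator bookkeeping", {
  sim <- simulate_expression(synthetic_spec(
    n_tumor = 10, n_normal = 10, n_probes = 100,
    planted = data.frame(role = character(), delta = numeric(),
                         f = numeric()),
    seed = 11))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(sim$dataset, path)
  back <- read_expression_tsv(
    path, structure(sim$dataset$labels, names = sim$dataset$sample_ids))
  expect_equal(colMeans(back$values), sim$truth$column_means,
               tolerance = 1e-12)
  # reading never mutates the fixture on disk
  before <- tools::md5sum(path)
  invisible(read_expression_tsv(
    path, structure(sim$dataset$labels, names = sim$dataset$sample_ids)))
  expect_identical(tools::md5sum(path), before)
})

test_that("parse errors name the offending cell; imputation fills per-class means", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2\ts3\ts4",
               "p1\t1.0\t2.0\t3.0\t4.0",
               "p2\t5.0\t\t6.0\t7.0",
               "p3\t1\t2\t3\t4"), path)
  labels <- c(s1 = "tumor", s2 = "tumor", s3 = "normal", s4 = "normal")
  err <- expect_error(read_expression_tsv(path, labels),
                      class = "markertree_parse_error")
  expect_match(conditionMessage(err), "p2")
  expect_match(conditionMessage(err), "s2")
  ds <- read_expression_tsv(path, labels, impute_missing = TRUE)
  expect_equal(ds$values["p2", "s2"], 5.0)  # tumor-class mean of p2

  writeLines(c("probe_id\ts1\ts2", "p1\t1.0\toops"), path)
  err2 <- expect_error(read_expression_tsv(path, labels[1:2]),
                       class = "markertree_parse_error")
  expect_match(conditionMessage(err2), "oops")
  writeLines(c("probe_id\ts1\ts2", "p1\t1.0\t2.0"), path)
  expect_error(read_expression_tsv(path, c(s1 = "tumor")),
               class = "markertree_label_error")
})

test_that("series-matrix parsing matches the TSV reader and keeps headers", {
  path <- withr::local_tempfile(fileext = ".txt")
  labels <- c(GSM1 = "tumor", GSM2 = "tumor", GSM3 = "normal",
              GSM4 = "normal")
  writeLines(c(
    "!Series_title\t\"synthetic miniature\"",
    "!Series_platform_id\t\"GPL96\"",
    "!series_matrix_table_begin",
    "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"\t\"GSM3\"\t\"GSM4\"",
    "\"201091_s_at\"\t7.9\t8.1\t6.2\t6.0",
    "\"201092_at\"\t5.5\t5.6\t5.4\t5.3",
    "\"201093_x_at\"\t9.0\t9.2\t9.1\t8.9",
    "!series_matrix_table_end"), path)
  ds <- read_series_matrix(path, labels)
  expect_equal(dim(ds), c(3L, 4L))
  expect_identical(ds$sample_ids, names(labels))
  expect_length(ds$meta$series_header, 2L)

  # the same table as a plain TSV parses to the same dataset
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tGSM1\tGSM2\tGSM3\tGSM4",
               "201091_s_at\t7.9\t8.1\t6.2\t6.0",
               "201092_at\t5.5\t5.6\t5.4\t5.3",
               "201093_x_at\t9.0\t9.2\t9.1\t8.9"), tsv)
  ds2 <- read_expression_tsv(tsv, labels)
  expect_equal(ds$values, ds2$values)
  expect_identical(ds$labels, ds2$labels)

  # degenerate files
  writeLines(c("!series_matrix_table_begin",
               "\"ID_REF\"\t\"GSM1\"", "\"p\"\t1.0"), path)
  expect_error(read_series_matrix(path, labels),
               class = "markertree_format_error")
  writeLines(c("!series_matrix_table_begin",
               "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"", "\"p\"\t1.0",
               "!series_matrix_table_end"), path)
  expect_error(read_series_matrix(path, labels),
               class = "markertree_parse_error")
})

test_that("artifact serialization round-trips every declared type", {
  sim <- simulate_expression(synthetic_spec(
    n_tumor = 8, n_normal = 8, n_probes = 30,
    planted = data.frame(role = "single_marker", delta = 5, f = NA),
    seed = 3))
  ds <- sim$dataset
  de <- prefilter(ds, alpha = 0.01)
  fit <- c45(ds, features = ds$probe_ids[1:5])
  rules <- extract_rules(fit)
  tr <- sffs(ds, candidates = ds$probe_ids[1:6], max_iter = 3)
  cv <- loocv(ds, features = sim$truth$planted$probe_id)

  d <- withr::local_tempdir()
  # tree: identical predictions after the round trip
  write_artifact(fit, file.path(d, "tree.json"))
  fit2 <- read_artifact(file.path(d, "tree.json"))
  newx <- matrix(rnorm(100 * 5, 8), 100, 5,
                 dimnames = list(NULL, ds$probe_ids[1:5]))
  expect_identical(predict(fit, newx), predict(fit2, newx))
  expect_equal(fit2$nodes$threshold, fit$nodes$threshold, tolerance = 1e-12)

  # rules: schema and field-exact round trip
  write_artifact(rules, file.path(d, "rules.tsv"))
  header <- strsplit(readLines(file.path(d, "rules.tsv"), n = 1), "\t")[[1]]
  expect_identical(header, c("conditions", "class", "covered",
                             "misclassified"))
  rules2 <- read_artifact(file.path(d, "rules.tsv"))
  expect_identical(rules2$class, rules$class)
  expect_identical(rules2$covered, rules$covered)
  expect_equal(rules2$conditions, rules$conditions, tolerance = 1e-12)

  # selection trace
  write_artifact(tr, file.path(d, "trace.json"))
  tr2 <- read_artifact(file.path(d, "trace.json"))
  expect_equal(tr2$steps, tr$steps, tolerance = 1e-12)
  expect_identical(tr2$selected, tr$selected)

  # cv result
  write_artifact(cv, file.path(d, "cv.json"))
  cv2 <- read_artifact(file.path(d, "cv.json"))
  expect_identical(unclass(cv2$confusion), unclass(cv$confusion))
  expect_equal(cv2$accuracy, cv$accuracy, tolerance = 1e-12)
  expect_equal(cv2$predictions, cv$predictions)

  # DE table
  write_artifact(de, file.path(d, "de.tsv"))
  de2 <- read_artifact(file.path(d, "de.tsv"))
  expect_identical(de2$kept, de$kept)
  expect_equal(de2$records$adj_p, de$records$adj_p, tolerance = 1e-12)

  expect_error(write_artifact(list(1), file.path(d, "x.json")),
               class = "markertree_usage_error")
})
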
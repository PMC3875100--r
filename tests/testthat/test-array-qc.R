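make_spots <- function(fg, bg = 100, sd = 10, controls = 0) {
  n <- length(fg)
  data.frame(spot_id = sprintf("spot%03d", seq_len(n)), fg_median = fg,
             bg_median = rep_len(bg, n), bg_sd = rep_len(sd, n),
             is_control = seq_len(n) <= controls)
}

test_that("Present call sits exactly at background + 3 sd and is monotone", {
  expect_true(present_flag(100, 70, 10))   # boundary 70 + 30
  expect_false(present_flag(99.9, 70, 10))
  expect_true(present_flag(50, 10, 0))     # zero-sd degenerate
  expect_error(present_flag(-1, 10, 1), class = "markertree_domain_error")

  set.seed(5)
  fg <- runif(200, 0, 300); bg <- runif(200, 0, 100); sd <- runif(200, 0, 30)
  base <- present_flag(fg, bg, sd)
  # monotone: nondecreasing in fg, nonincreasing in bg and sd
  expect_true(all(present_flag(fg + 1, bg, sd) >= base))
  expect_true(all(present_flag(fg, bg + 1, sd) <= base))
  expect_true(all(present_flag(fg, bg, sd + 1) <= base))
})

test_that("basic QC tolerates one outlying parameter but not two", {
  base <- data.frame(array_id = sprintf("a%02d", 1:10),
                     pct_present = rep(80, 10),
                     mean_present_intensity = rep(500, 10),
                     control_cv = rep(0.1, 10))
  all_pass <- basic_qc(base)
  expect_true(all(all_pass$basic_pass))  # IQR = 0, all values at quartiles

  one <- base; one$pct_present[10] <- 5
  r1 <- basic_qc(one)
  expect_true(all(r1$basic_pass))
  expect_identical(r1$outlier_params[[10]], "pct_present")

  two <- one; two$control_cv[10] <- 3
  r2 <- basic_qc(two)
  expect_false(r2$basic_pass[10])
  expect_true(all(r2$basic_pass[1:9]))
  expect_setequal(r2$outlier_params[[10]], c("pct_present", "control_cv"))

  # invariant under array reordering
  perm <- sample(10)
  r3 <- basic_qc(two[perm, ])
  expect_identical(r3$basic_pass, r2$basic_pass[perm])

  expect_error(basic_qc(base[1:3, ]),
               class = "markertree_insufficient_data_error")
})

test_that("array report computes the three quality parameters", {
  spots <- make_spots(fg = c(200, 200, 50, 50), bg = 100, sd = 10,
                      controls = 2)
  rep1 <- array_qc_report(spots, "a1")
  expect_equal(rep1$pct_present, 50)           # 2 of 4 >= 130
  expect_equal(rep1$mean_present_intensity, 200)
  expect_equal(rep1$control_cv, sd(c(200, 200)) / 200)
})

test_that("reproducibility check counts 2-fold probes and applies strict cuts", {
  set.seed(9)
  a <- runif(50, 100, 1000)
  same <- reproducibility_check(a, a)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$two_fold_pct, 0)
  expect_true(same$pass)

  prop <- reproducibility_check(2.01 * a, a)
  expect_equal(prop$two_fold_pct, 100)
  expect_false(prop$pass)  # perfectly correlated but every ratio > 2

  b <- a
  b[1:5] <- 3 * b[1:5]  # exactly 10% of probes tripled
  r <- reproducibility_check(b, a)
  expect_equal(r$two_fold_pct, 10)
  # brute-force recount
  expect_equal(r$two_fold_pct, 100 * sum(b / a > 2 | b / a < 0.5) / 50)
  expect_identical(r$pass, r$pearson_r > 0.95)
  # symmetry of the 2-fold percentage
  expect_equal(reproducibility_check(a, b)$two_fold_pct, r$two_fold_pct)

  expect_error(reproducibility_check(rep(1, 5), a[1:5]),
               class = "markertree_domain_error")  # zero variance
  expect_error(reproducibility_check(c(-1, 2, 3), c(1, 2, 3)),
               class = "markertree_domain_error")  # nonpositive intensity
})

test_that("present-union filter is the elementwise OR over qualified arrays", {
  set.seed(3)
  masks <- matrix(runif(200) < 0.3, 50, 4,
                  dimnames = list(sprintf("p%02d", 1:50), NULL))
  expect_identical(present_union_filter(masks),
                   apply(masks, 1, any))

  one_of_many <- matrix(FALSE, 10, 34)
  one_of_many[3, 17] <- TRUE
  inc <- present_union_filter(one_of_many)
  expect_true(inc[3])
  expect_false(any(inc[-3]))

  named <- lapply(1:3, function(i) {
    m <- runif(10) < 0.5
    names(m) <- sprintf("p%02d", 1:10)
    m
  })
  expect_identical(present_union_filter(named),
                   Reduce(`|`, named))
  bad <- named
  names(bad[[2]])[1] <- "other"
  expect_error(present_union_filter(bad),
               class = "markertree_alignment_error")
})

test_that("intensity histogram conserves spot counts", {
  spots <- make_spots(runif(500, 0, 1000))
  h <- intensity_histogram(spots, bins = 20)
  expect_equal(sum(h$count), 500)
  expect_equal(nrow(h), 20)
})
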
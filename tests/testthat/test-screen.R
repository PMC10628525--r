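test_that("stratified split reproduces the published arithmetic", {
  labels <- c(rep("pCR", 78), rep("non-pCR", 85))
  sp <- stratified_split(labels, seed = 1)
  expect_length(sp$train, 109L)
  expect_length(sp$test, 54L)
  expect_identical(sum(labels[sp$train] == "pCR"), 52L)
  expect_identical(sum(labels[sp$train] == "non-pCR"), 57L)
  expect_identical(sum(labels[sp$test] == "pCR"), 26L)
  expect_identical(sum(labels[sp$test] == "non-pCR"), 28L)
  expect_length(intersect(sp$train, sp$test), 0L)
  # 3/3 cohort: 2+2 train, 1+1 test
  sp2 <- stratified_split(rep(c("pCR", "non-pCR"), each = 3), seed = 4)
  expect_length(sp2$train, 4L)
  expect_length(sp2$test, 2L)
  expect_identical(stratified_split(labels, seed = 7),
                   stratified_split(labels, seed = 7))
  expect_false(identical(stratified_split(labels, seed = 7)$train,
                         stratified_split(labels, seed = 8)$train))
  expect_error(stratified_split(c("a", "a", "b"), seed = 1), ">= 2")
})

test_that("AUC matches hand values and the two oracles", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = 1), 1)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 1, 0, 1), positive = 1), 0.75)
  expect_equal(auc(rep(2, 8), rep(c(0, 1), 4), positive = 1), 0.5)
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    sc <- sample(c(rnorm(n), round(rnorm(n), 0)), n)  # mix in ties
    lb <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
    a <- auc(sc, lb, positive = 1)
    expect_equal(a, oracle_auc_pairs(sc, lb == 1), tolerance = 1e-12)
    expect_equal(a, oracle_auc_trapezoid(sc, lb == 1), tolerance = 1e-12)
    # label flip maps a -> 1 - a
    expect_equal(auc(sc, 1 - lb, positive = 1), 1 - a, tolerance = 1e-12)
  }
  expect_error(auc(1:4, c(1, 1, 1, 1), positive = 1), "both classes")
})

test_that("DeLong CI brackets the AUC and has near-nominal null coverage", {
  set.seed(15)
  sc <- c(rnorm(40), rnorm(40, 1)); lb <- rep(c(0, 1), each = 40)
  ci <- auc_ci95(sc, lb, positive = 1)
  a <- attr(ci, "auc")
  expect_true(ci[1] <= a && a <= ci[2])
  expect_true(ci[1] >= 0 && ci[2] <= 1)
  # perfect separation: upper bound 1, flagged degenerate
  ci2 <- auc_ci95(c(1:20, 101:120), rep(c(0, 1), each = 20), positive = 1)
  expect_equal(ci2[2], 1)
  expect_true(attr(ci2, "degenerate"))
  # Monte-Carlo coverage under the null
  cover <- vapply(1:1000, function(i) {
    sc <- rnorm(80); lb <- rep(c(0, 1), 40)
    ci <- auc_ci95(sc, lb, positive = 1)
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})

test_that("rank-sum test: exact enumeration and approximation behaviour", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12)), 0.1)
  # identical samples (all ties -> normal approximation): p = 1
  expect_equal(rank_sum_test(rep(1:5, 2), rep(1:5, 2)), 1)
  set.seed(16)
  expect_lt(rank_sum_test(rnorm(200, 2), rnorm(200)), 1e-6)
  # exact branch agrees with wilcox.test's exact distribution
  x <- c(0.3, 1.7, 2.2, 5.1); y <- c(0.9, 3.3, 4.0)
  expect_equal(rank_sum_test(x, y),
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("screen applies the inclusive dual-cohort rule with training orientation", {
  set.seed(18)
  n <- 90
  labels <- rep(c("pCR", "non-pCR"), each = n / 2)
  pos <- labels == "pCR"
  tab <- data.frame(
    subject_id = sprintf("S%02d", 1:n), response = labels,
    strong = rnorm(n) + 2.5 * pos,         # clearly selected
    inverted = rnorm(n) - 2.5 * pos,       # selected after orientation
    null1 = rnorm(n),                      # not selected
    check.names = FALSE)
  sp <- stratified_split(labels, seed = 2)
  res <- screen_features(tab, sp, threshold = 0.70)
  expect_identical(res$selected[res$feature == "strong"], TRUE)
  expect_identical(res$selected[res$feature == "inverted"], TRUE)
  expect_identical(res$direction[res$feature == "inverted"], -1)
  expect_identical(res$selected[res$feature == "null1"], FALSE)
  expect_true(all(res$auc_train >= 0.5))
  expect_true(all(res$ci_train_lo <= res$auc_train &
                    res$auc_train <= res$ci_train_hi))
})
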
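make_table <- function(n = 120, signal = 2, seed = 20) {
  # minimal synthetic feature table with the published column naming:
  # FO blocks for both regions; the Tumor RD-C4BL block carries signal
  set.seed(seed)
  labels <- rep(c("pCR", "non-pCR"), length.out = n)
  pos <- labels == "pCR"
  fo <- paste0("FO_", c("Minimum", "Maximum", "Mean", "Standard.Deviation",
                        "Percentile.1", "Percentile.5", "Percentile.95",
                        "Percentile.99", "Skewness", "Kurtosis"))
  tab <- data.frame(subject_id = sprintf("S%03d", 1:n), response = labels,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (reg in c("Peritumoral", "Tumor"))
    for (blk in c("BL", "C2", "C4", "AD-C4BL", "RD-C4BL"))
      for (f in fo) {
        v <- rnorm(n)
        if (reg == "Tumor" && blk == "RD-C4BL" && f == "FO_Mean")
          v <- v - signal * pos
        tab[[paste0(reg, "_DCE_", blk, "_", f)]] <- v
      }
  tab
}

test_that("model names parse to regions, blocks and class", {
  s <- parse_model_name("Tumoral_DCE_AD-C4BL_FO")
  expect_identical(s$regions, "Tumoral")
  expect_identical(s$blocks, "AD-C4BL")
  expect_identical(s$feature_class, "FO")
  big <- parse_model_name(paste0("Peritumoral_Tumoral_DCE_BL_C2_C4_AD-C2BL_",
                                 "RD-C2BL_AD-C4BL_RD-C4BL_AD-C4C2_RD-C4C2_FO"))
  expect_identical(big$regions, c("Peritumoral", "Tumoral"))
  expect_length(big$blocks, 9L)
  expect_identical(parse_model_name("Tumoral_DCE_C2_FO_GLCM")$feature_class,
                   "both")
  expect_identical(model_spec("Tumoral", "C2", "FO")$name, "Tumoral_DCE_C2_FO")
  expect_error(parse_model_name("Tumoral_C2_FO"), "DCE")
})

test_that("build_design resolves the documented column counts and standardizes", {
  # milder pCR shrinkage keeps C4 masks > 1 voxel, so no subject is
  # dropped for missing SD/skewness/kurtosis
  cohort <- small_cohort(n_pcr = 9, n_nonpcr = 9, seed = 23,
                         decline_pcr = c(1, 0.8, 0.6))
  tab <- cohort_feature_table(cohort)
  sp <- stratified_split(tab$response, seed = 3)
  d1 <- build_design("Peritumoral_DCE_C4_FO", tab, sp)
  expect_identical(ncol(d1$X_train), 10L)
  d2 <- build_design("Peritumoral_Tumoral_DCE_BL_C2_C4_FO", tab, sp)
  expect_identical(ncol(d2$X_train), 60L)
  expect_equal(unname(colMeans(d2$X_train)), rep(0, 60), tolerance = 1e-10)
  expect_equal(unname(apply(d2$X_train, 2, sd)), rep(1, 60), tolerance = 1e-10)
  d3 <- build_design("Tumoral_DCE_C4_FO_GLCM", tab, sp)
  expect_identical(ncol(d3$X_train) + length(d3$dropped_columns), 310L)
  expect_error(build_design("Tumoral_DCE_C4_FO", tab[1:8, ],
                            list(train = 1:6, test = 7:8)), "training subjects")
})

test_that("elastic net recovers a planted sparse effect and is deterministic", {
  set.seed(24)
  n <- 120
  X <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(NULL, paste0("V", 1:21)))
  y <- rep(c(0L, 1L), each = n / 2)
  X[, 1] <- X[, 1] + 2.2 * y
  X <- scale(X)
  fit <- fit_elastic_net_cv(X, y, seed = 5)
  expect_true("V1" %in% names(fit$coefficients))
  null_zeroed <- sum(!paste0("V", 2:21) %in% names(fit$coefficients))
  expect_gte(null_zeroed, 16L)   # >= 80% of null columns exactly zero
  fit2 <- fit_elastic_net_cv(X, y, seed = 5)
  expect_identical(fit$alpha, fit2$alpha)
  expect_identical(fit$lambda, fit2$lambda)
  expect_equal(fit$coefficients, fit2$coefficients)
  expect_gt(fit$cv_mean_auc, 0.8)
})

test_that("the fully-shrunk end of the path has zero coefficients", {
  set.seed(25)
  X <- scale(matrix(rnorm(60 * 5), 60, 5))
  colnames(X) <- paste0("V", 1:5)
  y <- rep(c(0L, 1L), 30)
  fit <- fit_elastic_net_cv(X, y, seed = 1)
  path <- fit$refit_path
  beta_top <- as.matrix(coef(path, s = max(path$lambda) * 2))[-1, 1]
  expect_true(all(beta_top == 0))
  # shrinkage monotonicity along the returned path
  nz <- path$df
  expect_true(all(diff(nz) >= 0 | diff(path$lambda) < 0))
})

test_that("evaluate_model: test-equals-train sanity and null behaviour", {
  tab <- make_table(n = 120, signal = 2)
  sp <- stratified_split(tab$response, seed = 6)
  des <- build_design("Tumoral_DCE_RD-C4BL_FO", tab, sp)
  fit <- fit_elastic_net_cv(des$X_train, des$y_train, seed = 6)
  ev_tr <- evaluate_model(fit, des$X_train, des$y_train)
  expect_equal(ev_tr$auc_test, fit$auc_train, tolerance = 1e-12)
  ev_te <- evaluate_model(fit, des$X_test, des$y_test)
  expect_gt(ev_te$auc_test, 0.75)   # planted effect recovered out of sample
})

test_that("run_model_suite returns 20 default rows and flags with the strict dual rule", {
  tab <- make_table(n = 120, signal = 2)
  sp <- stratified_split(tab$response, seed = 7)
  # restrict to models resolvable from the FO blocks present in make_table
  suite <- run_model_suite(table = tab, split = sp, seed = 7)
  expect_identical(nrow(suite), 20L)
  expect_identical(suite$model[5], "Tumoral_DCE_AD-C4BL_FO")
  ok <- !is.na(suite$auc_test)
  expect_true(any(ok))
  expect_identical(suite$flagged[ok],
                   (suite$auc_train[ok] >= 0.75 & suite$auc_test[ok] >= 0.75))
  # rows whose blocks are absent from this reduced table fail gracefully
  expect_true(all(!suite$flagged[!ok]))
  rd <- suite[suite$model == "Tumoral_DCE_RD-C4BL_FO", ]
  expect_gt(rd$auc_test, 0.75)
})
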
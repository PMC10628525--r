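test_that("quantization: one level per value, constant ROI, histogram oracle", {
  expect_identical(quantize_roi(c(0, 1, 2, 3), 4), c(1L, 2L, 3L, 4L))
  expect_identical(quantize_roi(rep(2.5, 10), 8), rep(1L, 10))
  set.seed(10)
  # dyadic values make the bin-edge arithmetic exact in floating point
  x <- c(0, 1, sample(seq(0, 1, by = 1 / 64), 500, replace = TRUE))
  q <- quantize_roi(x, 8)
  h <- hist(x, breaks = seq(0, 1, length.out = 9), plot = FALSE,
            right = FALSE)$counts  # [lo, hi) bins; max joins the top bin
  expect_identical(tabulate(q, 8), as.integer(h))
  expect_error(quantize_roi(numeric(0), 8), "empty")
})

test_that("first-order features match direct formulas and handle edge cases", {
  f <- first_order_features(c(1, 2, 3, 4))
  expect_equal(unname(f[c("FO_Minimum", "FO_Maximum", "FO_Mean")]),
               c(1, 4, 2.5))
  expect_equal(unname(f["FO_Skewness"]), 0)
  fc <- first_order_features(rep(7, 5))
  expect_equal(unname(fc["FO_Standard.Deviation"]), 0)
  expect_equal(unname(fc[c("FO_Minimum", "FO_Maximum", "FO_Mean",
                           "FO_Percentile.95")]), rep(7, 4))
  set.seed(3)
  x <- rnorm(1000)
  f2 <- first_order_features(x)
  n <- length(x); m <- mean(x)
  expect_equal(unname(f2["FO_Standard.Deviation"]),
               sqrt(sum((x - m)^2) / (n - 1)))
  expect_equal(unname(f2["FO_Percentile.95"]),
               unname(quantile(x, 0.95, type = 7)))
  g1 <- mean((x - m)^3) / mean((x - m)^2)^1.5
  expect_equal(unname(f2["FO_Skewness"]), g1 * sqrt(n * (n - 1)) / (n - 2))
  expect_equal(unname(f2["FO_Kurtosis"]),
               mean((x - m)^4) / mean((x - m)^2)^2)
  expect_true(all(is.na(first_order_features(numeric(0)))))
  f1 <- first_order_features(5)
  expect_true(is.na(f1["FO_Standard.Deviation"]) && is.na(f1["FO_Skewness"]))
  expect_equal(unname(f1["FO_Mean"]), 5)
})

test_that("GLCM matrix matches brute-force pair enumeration (incl. the 4x4 toy)", {
  toy <- array(0L, dim = c(4, 4, 1))
  toy[, , 1] <- rbind(c(1, 1, 2, 2), c(1, 1, 2, 2), c(3, 3, 4, 4), c(3, 3, 4, 4))
  P <- glcm_matrix(toy, offset = c(0, 1, 0), n_levels = 4)
  expect_equal(unclass(P)[1:4, 1:4], oracle_glcm(toy, c(0, 1, 0), 4),
               ignore_attr = TRUE)
  expect_equal(sum(P), 1)
  expect_identical(unclass(P), t(unclass(P)))
  set.seed(21)
  offs <- glcm_offsets()
  for (rep in 1:4) {
    lv <- array(sample(0:4, 5^3, replace = TRUE), dim = c(5, 5, 5))
    d <- offs[sample(13, 1), ]
    P <- glcm_matrix(lv, offset = d, n_levels = 4)
    O <- oracle_glcm(lv, d, 4)
    if (is.null(O)) {
      expect_true(attr(P, "empty"))
    } else {
      expect_equal(unclass(P), O, ignore_attr = TRUE, tolerance = 1e-12)
      expect_equal(sum(P), 1)
    }
  }
})

test_that("constant ROI gives the degenerate single-entry GLCM and scalars", {
  lv <- array(1L, dim = c(4, 4, 4))
  P <- glcm_matrix(lv, offset = c(1, 0, 0), n_levels = 8)
  expect_equal(P[1, 1], 1)
  s <- glcm_scalar_features(P)
  expect_equal(unname(s[c("Energy", "Entropy", "Contrast",
                          "Maximum.Probability", "Dissimilarity")]),
               c(1, 0, 0, 1, 0))
  expect_true(is.na(s["Correlation"]))
  # flagged-empty matrix: all scalars missing
  off_mask <- array(0L, dim = c(4, 4, 4)); off_mask[1, 1, 1] <- 1L
  Pe <- glcm_matrix(off_mask, offset = c(1, 0, 0), n_levels = 4)
  expect_true(attr(Pe, "empty"))
  expect_true(all(is.na(glcm_scalar_features(Pe))))
})

test_that("GLCM scalars: 2x2 hand values and the direct-sum oracle", {
  P <- matrix(0.25, 2, 2)
  s <- glcm_scalar_features(P)
  expect_equal(unname(s["Energy"]), 0.25)
  expect_equal(unname(s["Entropy"]), 2)   # log2(4)
  expect_equal(unname(s["Contrast"]), 0.5)
  set.seed(31)
  for (ng in c(3, 6)) {
    M <- matrix(rexp(ng^2), ng, ng)
    M <- M + t(M); M <- M / sum(M)
    impl <- glcm_scalar_features(M)
    orc <- oracle_glcm_scalars(M)
    expect_equal(unname(impl), unname(orc[names(impl)]), tolerance = 1e-12)
  }
})

test_that("rotation-invariant aggregation follows the direct formulas", {
  expect_equal(unname(rotation_invariant_aggregate(rep(3.5, 13))), c(3.5, 0, 0))
  v <- c(rep(0, 12), 1)
  expect_equal(unname(rotation_invariant_aggregate(v)[1:2]), c(1 / 13, 1))
  set.seed(8)
  x <- rnorm(13)
  a <- rotation_invariant_aggregate(x)
  expect_equal(unname(a), c(mean(x), max(x) - min(x), mean((x - mean(x))^2)))
  x[c(2, 9)] <- NA
  a2 <- rotation_invariant_aggregate(x)
  xx <- x[!is.na(x)]
  expect_equal(unname(a2), c(mean(xx), max(xx) - min(xx),
                             mean((xx - mean(xx))^2)))
  expect_true(all(is.na(rotation_invariant_aggregate(rep(NA_real_, 13)))))
})

test_that("extraction yields exactly 310 well-named features", {
  set.seed(2)
  v <- array(rnorm(16^3, 50, 10), dim = c(16, 16, 16))
  m <- array(0L, dim = dim(v)); m[4:13, 5:12, 6:11] <- 1L
  f <- extract_features(v, m)
  expect_length(f, 310L)
  expect_identical(sum(startsWith(names(f), "FO_")), 10L)
  expect_identical(sum(startsWith(names(f), "GLCM_")), 300L)
  expect_identical(anyDuplicated(names(f)), 0L)
  for (lv in c(8, 16, 32, 64, 256))
    expect_identical(sum(grepl(paste0("\\.N", lv, "$"), names(f))), 60L)
  expect_warning(fe <- extract_features(v, array(0L, dim = dim(v))), "empty")
  expect_true(all(is.na(fe)))
  expect_length(fe, 310L)
})

test_that("intensity shift leaves GLCM features unchanged and shifts FO mean", {
  set.seed(12)
  v <- array(rnorm(12^3), dim = c(12, 12, 12))
  m <- array(as.integer(runif(12^3) < 0.4), dim = c(12, 12, 12))
  f1 <- extract_features(v, m)
  f2 <- extract_features(v + 17.3, m)
  glcm <- startsWith(names(f1), "GLCM_")
  expect_equal(f2[glcm], f1[glcm], tolerance = 1e-9)
  expect_equal(unname(f2["FO_Mean"] - f1["FO_Mean"]), 17.3)
  expect_equal(unname(f2["FO_Standard.Deviation"]),
               unname(f1["FO_Standard.Deviation"]))
})

test_that("90-degree rotations on an isotropic grid leave all 300 aggregates unchanged", {
  set.seed(13)
  v <- array(rnorm(10^3), dim = c(10, 10, 10))
  m <- array(0L, dim = dim(v)); m[3:8, 2:9, 4:9] <- 1L
  f <- extract_features(v, m)
  rot_z <- function(a) aperm(a, c(2, 1, 3))[, dim(a)[1]:1, , drop = FALSE]
  rot_x <- function(a) aperm(a, c(1, 3, 2))[, , dim(a)[2]:1, drop = FALSE]
  glcm <- startsWith(names(f), "GLCM_")
  for (rot in list(rot_z, rot_x)) {
    fr <- extract_features(rot(v), array(as.integer(rot(m)), dim = dim(rot(m))))
    expect_equal(fr[glcm], f[glcm], tolerance = 1e-10)
  }
})
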
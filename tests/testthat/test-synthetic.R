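cfg0 <- cohort_config(n_pcr = 2, n_nonpcr = 2,
                      image_shape = c(24L, 24L, 12L), spacing_mm = c(1, 1, 2),
                      tumor_radius_range_mm = c(4, 7), seed = 5)

test_that("decay factors apply exactly when noise is zero", {
  cfg <- cohort_config(n_pcr = 1, n_nonpcr = 1, noise_sd = 0,
                       decline_pcr = c(1, 0.5, 0.1),
                       image_shape = c(32L, 32L, 16L), spacing_mm = c(1, 1, 2),
                       tumor_radius_range_mm = c(5, 8), seed = 2)
  s <- generate_subject(cfg, "pCR", 99)
  mean_bl <- mean(s$timepoints$BL$volume$data[s$timepoints$BL$mask$data == 1])
  mean_c4 <- mean(s$timepoints$C4$volume$data[s$timepoints$C4$mask$data == 1])
  # in-mask intensity is enhancement x texture: ratio 0.1 up to the
  # texture-mean difference between the full and shrunken ellipsoid
  expect_equal(mean_c4 / mean_bl, 0.1, tolerance = 0.15)
})

test_that("generation is a pure function of (config, response, seed)", {
  a <- generate_subject(cfg0, "non-pCR", 123)
  b <- generate_subject(cfg0, "non-pCR", 123)
  expect_identical(a$timepoints$BL$volume$data, b$timepoints$BL$volume$data)
  expect_identical(a$timepoints$C4$mask$data, b$timepoints$C4$mask$data)
  expect_identical(a$reader2_masks$C2$data, b$reader2_masks$C2$data)
  c <- generate_subject(cfg0, "non-pCR", 124)
  expect_false(identical(a$timepoints$BL$volume$data,
                         c$timepoints$BL$volume$data))
})

test_that("zero C4 enhancement yields a tumor-bed placeholder mask", {
  cfg <- cohort_config(n_pcr = 1, n_nonpcr = 1,
                       decline_pcr = c(1, 0.5, 0),
                       image_shape = c(24L, 24L, 12L), spacing_mm = c(1, 1, 2),
                       tumor_radius_range_mm = c(4, 6), seed = 3)
  s <- generate_subject(cfg, "pCR", 7)
  expect_true(s$timepoints$C4$tumor_bed)
  expect_gt(sum(s$timepoints$C4$mask$data), 0)
  expect_identical(s$timepoints$C4$mask$data, s$timepoints$C2$mask$data)
  expect_false(s$timepoints$BL$tumor_bed)
})

test_that("tumor larger than the grid errors naming the dimension", {
  cfg <- cohort_config(n_pcr = 1, n_nonpcr = 1,
                       image_shape = c(16L, 16L, 16L), spacing_mm = c(1, 1, 1),
                       tumor_radius_range_mm = c(20, 20), seed = 1)
  expect_error(generate_subject(cfg, "pCR", 1), "dimension")
})

test_that("cohort has requested label counts and deterministic manifests", {
  cohort <- generate_cohort(cfg0)
  expect_length(cohort, 4L)
  labs <- vapply(cohort, function(s) s$response, character(1))
  expect_identical(sum(labs == "pCR"), 2L)
  expect_identical(attr(cohort, "labels"), labs)
  cohort2 <- generate_cohort(cfg0)
  expect_identical(cohort[[3]]$timepoints$C2$volume$data,
                   cohort2[[3]]$timepoints$C2$volume$data)
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("perturb_mask honors its shell contract", {
  m <- array(0L, dim = c(28, 28, 28))
  co <- (1:28) - 14.5
  r2 <- outer(outer(co^2, co^2, `+`), co^2, `+`)
  m[r2 <= 100] <- 1L  # radius-10 mm sphere at 1 mm spacing
  # magnitude 0 is the identity
  expect_identical(perturb_mask(m, c(1, 1, 1), 0, seed = 1)$data, m)
  p <- perturb_mask(m, c(1, 1, 1), 2, seed = 8)
  changed <- p$data != m
  expect_gt(sum(changed), 0)
  d_out <- distance_from_mask(m, c(1, 1, 1))
  d_in <- distance_from_mask(1L - m, c(1, 1, 1))
  expect_true(all(d_out[changed] <= 2 & d_in[changed] <= 2))
  dice <- 2 * sum(p$data & m) / (sum(p$data) + sum(m))
  expect_gt(dice, 0.7)
  expect_warning(pe <- perturb_mask(array(0L, dim = c(8, 8, 8)),
                                    c(1, 1, 1), 2, seed = 1), "empty")
  expect_identical(sum(pe$data), 0L)
})

test_that("cohort writes to NIfTI + manifest and reads back identically", {
  dir <- tempfile("cohort")
  cohort <- generate_cohort(cohort_config(
    n_pcr = 1, n_nonpcr = 1, image_shape = c(16L, 16L, 8L),
    spacing_mm = c(1, 1, 2), tumor_radius_range_mm = c(3, 5), seed = 9))
  man <- write_cohort(cohort, dir)
  expect_true(file.exists(man))
  back <- read_cohort(man)
  expect_length(back, 2L)
  expect_identical(back[[1]]$response, cohort[[1]]$response)
  expect_equal(back[[2]]$timepoints$C4$volume$data,
               cohort[[2]]$timepoints$C4$volume$data, tolerance = 1e-5)
  expect_identical(back[[2]]$timepoints$C4$mask$data,
                   cohort[[2]]$timepoints$C4$mask$data)
  expect_identical(back[[1]]$reader2_masks$BL$data,
                   cohort[[1]]$reader2_masks$BL$data)
  unlink(dir, recursive = TRUE)
})
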
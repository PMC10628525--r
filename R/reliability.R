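.feature_cols <- function(table) {
  setdiff(names(table), c("subject_id", "response"))
}

.align_tables <- function(a, b) {
  fc <- .feature_cols(a)
  if (!identical(fc, .feature_cols(b)))
    stop("feature tables have different columns")
  if (!is.null(a$subject_id) && !is.null(b$subject_id)) {
    if (!identical(as.character(a$subject_id), as.character(b$subject_id)))
      stop("feature tables cover different subjects (or different order)")
  } else if (nrow(a) != nrow(b)) {
    stop("feature tables have different numbers of subjects")
  }
  fc
}

#' Per-feature Pearson correlation between two readers
#'
#' Product-moment correlation of every feature across subjects, with
#' pairwise deletion of missing values. Features with fewer than 3
#' complete pairs or a constant value in either reader are missing.
#'
#' @param table_r1,table_r2 feature tables over the same subjects and
#'   columns (e.g. [cohort_feature_table()] for each reader's masks).
#' @return Named numeric vector of correlations.
#' @export
pearson_per_feature <- function(table_r1, table_r2) {
  fc <- .align_tables(table_r1, table_r2)
  vapply(fc, function(f) {
    x <- table_r1[[f]]; y <- table_r2[[f]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, numeric(1))
}

#' Per-feature Wilcoxon signed-rank test between two readers
#'
#' Two-sided paired signed-rank p-value per feature; zero differences are
#' dropped before ranking (classic Wilcoxon convention — identical
#' segmentations produce exact zeros for many features). When every
#' difference is zero the p-value is 1.
#'
#' @inheritParams pearson_per_feature
#' @return Named numeric vector of p-values.
#' @export
signed_rank_per_feature <- function(table_r1, table_r2) {
  fc <- .align_tables(table_r1, table_r2)
  vapply(fc, function(f) {
    x <- table_r1[[f]]; y <- table_r2[[f]]
    ok <- !is.na(x) & !is.na(y)
    d <- x[ok] - y[ok]
    d <- d[d != 0]
    if (length(d) == 0L) return(1)
    suppressWarnings(stats::wilcox.test(d, alternative = "two.sided")$p.value)
  }, numeric(1))
}

#' Interreader-to-cohort variance ratio per feature
#'
#' Paired-difference variance-components estimator: the intrareader
#' variance is half the mean squared reader-1 repeat difference, the
#' interreader variance is half the mean squared reader-1 vs reader-2
#' difference minus the intrareader component (clipped at 0), and the
#' ratio normalizes the interreader component by the cohort variance of
#' the feature (reader-1 values), so 0 means readers agree to within
#' repeat-measurement noise. `0/0` is defined as 0; a zero cohort
#' variance gives a missing ratio.
#'
#' @param table_r1 reader-1 feature table.
#' @param table_r1_repeat reader-1 repeat-segmentation feature table.
#' @param table_r2 reader-2 feature table.
#' @return Named numeric vector of nonnegative ratios.
#' @export
variance_ratio_per_feature <- function(table_r1, table_r1_repeat,
                                       table_r2) {
  fc <- .align_tables(table_r1, table_r2)
  .align_tables(table_r1, table_r1_repeat)
  vapply(fc, function(f) {
    x <- table_r1[[f]]; xr <- table_r1_repeat[[f]]; y <- table_r2[[f]]
    ok <- !is.na(x) & !is.na(xr) & !is.na(y)
    if (sum(ok) < 3L) return(NA_real_)
    x <- x[ok]; xr <- xr[ok]; y <- y[ok]
    intra <- 0.5 * mean((x - xr)^2)
    inter <- max(0, 0.5 * mean((x - y)^2) - intra)
    v <- stats::var(x)
    if (v == 0) {
      if (inter == 0) return(0)
      return(NA_real_)
    }
    inter / v
  }, numeric(1))
}

.feature_class_of <- function(feature_names) {
  cls <- ifelse(grepl("_FO_", feature_names), "FO",
                ifelse(grepl("_GLCM_", feature_names), "GLCM", NA))
  kind <- ifelse(grepl("_AD-", feature_names), "AD",
                 ifelse(grepl("_RD-", feature_names), "RD", "original"))
  paste(cls, kind, sep = "_")
}

#' Class-level reliability summary
#'
#' For each feature class (`FO`/`GLCM` crossed with
#' `original`/`AD`/`RD`): the fraction of features with Pearson r > 0.8
#' and the mean, median, SD and range of the variance ratios.
#'
#' @param pearson named vector from [pearson_per_feature()].
#' @param variance_ratio optional named vector from
#'   [variance_ratio_per_feature()] (same names).
#' @return `data.frame`, one row per feature class.
#' @export
summarize_reliability <- function(pearson, variance_ratio = NULL) {
  if (length(pearson) == 0L)
    return(data.frame(class = character(0), n = integer(0),
                      frac_r_gt_0.8 = numeric(0)))
  cls <- .feature_class_of(names(pearson))
  out <- lapply(sort(unique(cls)), function(cl) {
    idx <- cls == cl
    r <- pearson[idx]
    row <- data.frame(class = cl, n = sum(idx),
                      frac_r_gt_0.8 = mean(r > 0.8, na.rm = TRUE),
                      stringsAsFactors = FALSE)
    if (!is.null(variance_ratio)) {
      vr <- variance_ratio[names(pearson)[idx]]
      row$vr_mean <- mean(vr, na.rm = TRUE)
      row$vr_median <- stats::median(vr, na.rm = TRUE)
      row$vr_sd <- stats::sd(vr, na.rm = TRUE)
      row$vr_min <- suppressWarnings(min(vr, na.rm = TRUE))
      row$vr_max <- suppressWarnings(max(vr, na.rm = TRUE))
    }
    row
  })
  do.call(rbind, out)
}

#' Full interreader reliability analysis of a cohort
#'
#' Extracts feature tables with the primary, second-reader and (when
#' present) reader-1 repeat masks and computes per-feature Pearson r,
#' signed-rank p, variance ratios and the class-level summary.
#'
#' @param cohort list of `subject_record`s carrying `reader2_masks` (and
#'   optionally `reader1_repeat_masks`).
#' @param thickness_mm peritumoral thickness (mm). Default 10.
#' @param gray_levels gray-level counts.
#' @return List `pearson`, `signed_rank_p`, `variance_ratio` (or NULL),
#'   `summary`.
#' @export
interreader_analysis <- function(cohort, thickness_mm = 10,
                                 gray_levels = .default_gray_levels) {
  if (is.null(cohort[[1]]$reader2_masks))
    stop("cohort has no second-reader masks")
  t1 <- cohort_feature_table(cohort, thickness_mm, gray_levels)
  t2 <- cohort_feature_table(cohort, thickness_mm, gray_levels,
                             masks = function(rec, tp) rec$reader2_masks[[tp]])
  pr <- pearson_per_feature(t1, t2)
  sr <- signed_rank_per_feature(t1, t2)
  vr <- NULL
  if (!is.null(cohort[[1]]$reader1_repeat_masks)) {
    t1r <- cohort_feature_table(cohort, thickness_mm, gray_levels,
                                masks = function(rec, tp)
                                  rec$reader1_repeat_masks[[tp]])
    vr <- variance_ratio_per_feature(t1, t1r, t2)
  }
  list(pearson = pr, signed_rank_p = sr, variance_ratio = vr,
       summary = summarize_reliability(pr, vr))
}
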
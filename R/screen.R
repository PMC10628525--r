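#' Stratified 2:1 train/test split
#'
#' Splits subjects into training and testing sets preserving class
#' proportions: per class, round-half-up of `2n/3` subjects go to
#' training, the remainder to testing. With the study's 78 pCR / 85
#' non-pCR cohort this reproduces 52 + 57 = 109 training and
#' 26 + 28 = 54 testing subjects. Membership is deterministic given the
#' seed.
#'
#' @param labels per-subject response labels (two classes, >= 2 each).
#' @param seed integer seed for within-class shuffling.
#' @param ratio train:test ratio as length-2 numeric. Default `c(2, 1)`.
#' @return List with integer index vectors `train`, `test` and the seed.
#' @export
stratified_split <- function(labels, seed, ratio = c(2, 1)) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) stop("expected exactly 2 classes")
  counts <- table(labels)
  if (any(counts < 2L))
    stop("each class needs >= 2 subjects; got ",
         paste(counts, collapse = "/"))
  frac <- ratio[1] / sum(ratio)
  .with_seed(seed, {
    train <- integer(0)
    for (cl in classes) {
      idx <- which(labels == cl)
      n_train <- floor(length(idx) * frac + 0.5)  # round half up
      train <- c(train, sort(sample(idx, n_train)))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train),
         seed = as.integer(seed))
  })
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' `AUC = (#concordant pairs + 0.5 #ties) / (n1 * n0)`, computed from
#' midranks; identical to the trapezoidal area under the empirical ROC
#' curve. With `orient = TRUE` the reported value is `max(a, 1 - a)` and
#' the direction is returned as an attribute, matching the convention of
#' reporting unsigned feature AUCs.
#'
#' @param scores numeric predictor values (missing values dropped
#'   pairwise with their labels).
#' @param labels binary labels; `positive` names the positive class.
#' @param positive value of `labels` treated as positive. Default: for
#'   logical/0-1 labels, `TRUE`/1; otherwise `"pCR"` if present, else the
#'   first level.
#' @param orient report `max(a, 1 - a)` (default `FALSE`).
#' @return AUC in `[0, 1]`; attribute `direction` (+1 or -1) if oriented.
#' @export
auc <- function(scores, labels, positive = NULL, orient = FALSE) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  pos <- .positive_indicator(labels, positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("auc: both classes must be present")
  r <- rank(scores)  # midranks handle ties
  a <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (orient) {
    dir <- if (a >= 0.5) 1 else -1
    a <- max(a, 1 - a)
    attr(a, "direction") <- dir
  }
  a
}

.positive_indicator <- function(labels, positive = NULL) {
  if (is.null(positive)) {
    if (is.logical(labels)) positive <- TRUE
    else if (is.numeric(labels)) positive <- 1
    else if ("pCR" %in% labels) positive <- "pCR"
    else positive <- sort(unique(as.character(labels)))[1]
  }
  labels == positive
}

#' DeLong 95% confidence interval for a single AUC
#'
#' Nonparametric variance from the placement values
#' (structural-components estimator), normal interval truncated to
#' `[0, 1]`. A degenerate variance (AUC exactly 0 or 1) collapses the
#' interval, flagged via the `degenerate` attribute.
#'
#' @inheritParams auc
#' @return Length-2 numeric `c(lower, upper)` with attributes `auc` and
#'   `degenerate`.
#' @export
auc_ci95 <- function(scores, labels, positive = NULL) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  pos <- .positive_indicator(labels, positive)
  x <- scores[pos]; y <- scores[!pos]
  n1 <- length(x); n0 <- length(y)
  if (n1 == 0L || n0 == 0L) stop("auc_ci95: both classes must be present")
  # placement values via midranks (identical to the psi-average definition)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(n1)] - rank(x)) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(y)) / n1
  a <- mean(v10)
  s10 <- if (n1 > 1) stats::var(v10) else 0
  s01 <- if (n0 > 1) stats::var(v01) else 0
  se <- sqrt(s10 / n1 + s01 / n0)
  degenerate <- se == 0
  ci <- c(max(0, a - 1.959964 * se), min(1, a + 1.959964 * se))
  attr(ci, "auc") <- a
  attr(ci, "degenerate") <- degenerate
  ci
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when there are no ties and `n1 * n0 <= 400`;
#' otherwise the tie-corrected normal approximation (without continuity
#' correction, so identical samples give p = 1).
#'
#' @param x,y numeric samples for the two groups (nonempty).
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("rank_sum_test: both samples must be nonempty")
  n1 <- length(x); n0 <- length(y)
  r <- rank(c(x, y))
  ties <- any(duplicated(c(x, y)))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U of x
  if (!ties && n1 * n0 <= 400) {
    p <- if (w > n1 * n0 / 2)
      stats::pwilcox(w - 1, n1, n0, lower.tail = FALSE) * 2
    else
      stats::pwilcox(w, n1, n0) * 2
    return(min(1, p))
  }
  mu <- n1 * n0 / 2
  tie_tab <- table(r)
  n <- n1 + n0
  sigma2 <- n1 * n0 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 == 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Univariate dual-cohort AUC screen
#'
#' For every feature column: training and testing AUC (oriented on the
#' training cohort; the training direction is applied to the testing
#' cohort), DeLong 95% CIs, and the training-cohort Wilcoxon rank-sum
#' p-value. A feature is selected when
#' `auc_train >= threshold & auc_test >= threshold & p_train < 0.05`
#' (both bounds inclusive at the threshold).
#'
#' @param table feature `data.frame` from [cohort_feature_table()] (or
#'   any data frame whose non-feature columns are `subject_id`,
#'   `response`).
#' @param split a [stratified_split()] result.
#' @param threshold dual-cohort AUC threshold. Default 0.70.
#' @param positive positive class label. Default `"pCR"`.
#' @return `data.frame` with one row per feature: `feature`, `auc_train`,
#'   `ci_train_lo/hi`, `auc_test`, `ci_test_lo/hi`, `p_train`,
#'   `direction`, `selected`.
#' @export
screen_features <- function(table, split, threshold = 0.70,
                            positive = "pCR") {
  featcols <- setdiff(names(table), c("subject_id", "response"))
  labels <- table$response
  pos <- .positive_indicator(labels, positive)
  res <- lapply(featcols, function(fc) {
    v <- table[[fc]]
    vtr <- v[split$train]; ptr <- pos[split$train]
    vte <- v[split$test]; pte <- pos[split$test]
    ok_tr <- sum(!is.na(vtr) & ptr) > 0 && sum(!is.na(vtr) & !ptr) > 0
    ok_te <- sum(!is.na(vte) & pte) > 0 && sum(!is.na(vte) & !pte) > 0
    if (!ok_tr || !ok_te || stats::sd(vtr, na.rm = TRUE) %in% c(0, NA)) {
      return(data.frame(feature = fc, auc_train = NA_real_,
                        ci_train_lo = NA_real_, ci_train_hi = NA_real_,
                        auc_test = NA_real_, ci_test_lo = NA_real_,
                        ci_test_hi = NA_real_, p_train = NA_real_,
                        direction = NA_real_, selected = FALSE,
                        stringsAsFactors = FALSE))
    }
    a_tr <- auc(vtr, ptr, positive = TRUE, orient = TRUE)
    dir <- attr(a_tr, "direction")
    ci_tr <- auc_ci95(dir * vtr, ptr, positive = TRUE)
    a_te_raw <- auc(dir * vte, pte, positive = TRUE)
    ci_te <- auc_ci95(dir * vte, pte, positive = TRUE)
    p_tr <- rank_sum_test(vtr[ptr], vtr[!ptr])
    sel <- (as.numeric(a_tr) >= threshold) && (a_te_raw >= threshold) &&
      (p_tr < 0.05)
    data.frame(feature = fc, auc_train = as.numeric(a_tr),
               ci_train_lo = ci_tr[1], ci_train_hi = ci_tr[2],
               auc_test = a_te_raw, ci_test_lo = ci_te[1],
               ci_test_hi = ci_te[2], p_train = p_tr, direction = dir,
               selected = sel, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
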
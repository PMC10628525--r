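#' Declarative model specification
#'
#' A model is a feature-block combination encoded by its name,
#' `<Regions>_DCE_<Blocks>_<Class>`: region tokens `Peritumoral` and/or
#' `Tumoral`, block tokens among `BL, C2, C4, AD-C2BL, RD-C2BL, AD-C4BL,
#' RD-C4BL, AD-C4C2, RD-C4C2`, and feature class `FO`, `GLCM` or
#' `FO_GLCM` (both). `model_spec()` builds the spec from components,
#' `parse_model_name()` from a published-style name such as
#' `Tumoral_DCE_AD-C4BL_FO`.
#'
#' @param regions character subset of `c("Peritumoral", "Tumoral")`.
#' @param blocks character subset of the 9 block tokens.
#' @param feature_class `"FO"`, `"GLCM"` or `"both"`.
#' @return A `model_spec` (list with `name`, `regions`, `blocks`,
#'   `feature_class`).
#' @export
model_spec <- function(regions, blocks, feature_class = "FO") {
  regions <- match.arg(regions, c("Peritumoral", "Tumoral"),
                       several.ok = TRUE)
  blocks <- match.arg(blocks, .blocks, several.ok = TRUE)
  feature_class <- match.arg(feature_class, c("FO", "GLCM", "both"))
  cls_tok <- switch(feature_class, FO = "FO", GLCM = "GLCM",
                    both = "FO_GLCM")
  name <- paste(c(regions, "DCE", blocks, cls_tok), collapse = "_")
  structure(list(name = name, regions = regions, blocks = blocks,
                 feature_class = feature_class), class = "model_spec")
}

#' @param name a model name string.
#' @rdname model_spec
#' @export
parse_model_name <- function(name) {
  cls <- if (grepl("_FO_GLCM$", name)) "both"
  else if (grepl("_GLCM$", name)) "GLCM"
  else if (grepl("_FO$", name)) "FO"
  else stop("model name must end in _FO, _GLCM or _FO_GLCM: ", name)
  body <- sub("_(FO|GLCM|FO_GLCM)$", "", name)
  toks <- strsplit(body, "_")[[1]]
  dce <- which(toks == "DCE")
  if (length(dce) != 1L) stop("model name must contain one DCE token: ", name)
  regions <- toks[seq_len(dce - 1L)]
  blocks <- toks[(dce + 1L):length(toks)]
  model_spec(regions, blocks, cls)
}

#' The 20 published model specifications
#'
#' The 13 models reported as achieving dual-cohort AUC >= 0.75 plus the
#' 7 single/paired-time-point first-order models reported with AUC >
#' 0.70, parsed from their names.
#'
#' @return List of `model_spec`s, length 20.
#' @export
default_model_suite <- function() {
  names13 <- c(
    "Peritumoral_DCE_AD-C4BL_FO",
    "Peritumoral_DCE_RD-C4BL_FO",
    "Peritumoral_DCE_BL_C2_C4_FO",
    "Peritumoral_DCE_BL_C2_C4_AD-C2BL_RD-C2BL_AD-C4BL_RD-C4BL_AD-C4C2_RD-C4C2_FO",
    "Tumoral_DCE_AD-C4BL_FO",
    "Tumoral_DCE_RD-C4BL_FO",
    "Tumoral_DCE_BL_C4_AD-C4BL_RD-C4BL_FO",
    "Peritumoral_Tumoral_DCE_AD-C4BL_FO",
    "Peritumoral_Tumoral_DCE_RD-C4BL_FO",
    "Peritumoral_Tumoral_DCE_BL_C4_AD-C4BL_RD-C4BL_FO",
    "Peritumoral_Tumoral_DCE_C2_C4_AD-C4C2_RD-C4C2_FO",
    "Peritumoral_Tumoral_DCE_BL_C2_C4_FO",
    "Peritumoral_Tumoral_DCE_BL_C2_C4_AD-C2BL_RD-C2BL_AD-C4BL_RD-C4BL_AD-C4C2_RD-C4C2_FO")
  names7 <- c(
    "Peritumoral_DCE_C4_FO",
    "Peritumoral_DCE_BL_C4_FO",
    "Peritumoral_DCE_C2_C4_FO",
    "Tumoral_DCE_C2_FO",
    "Tumoral_DCE_C4_FO",
    "Tumoral_DCE_BL_C2_FO",
    "Tumoral_DCE_BL_C4_FO")
  lapply(c(names13, names7), parse_model_name)
}

.spec_columns <- function(spec, colnames_all) {
  prefixes <- .regions[spec$regions]  # Peritumoral -> Peritumoral, Tumoral -> Tumor
  classes <- switch(spec$feature_class, FO = "FO", GLCM = "GLCM",
                    both = c("FO", "GLCM"))
  cols <- unlist(lapply(prefixes, function(pref)
    lapply(spec$blocks, function(b)
      lapply(classes, function(cl) {
        pat <- paste0("^", pref, "_DCE_", b, "_", cl, "_")
        grep(pat, colnames_all, value = TRUE)
      }))), use.names = FALSE)
  unique(cols)
}

#' Build a standardized train/test design for a model spec
#'
#' Restricts the feature table to the spec's columns, standardizes every
#' column to zero mean / unit variance using training-set statistics only
#' (no test-set leakage), drops columns with zero training variance with
#' a warning, and drops subjects with any missing design value per model.
#'
#' @param spec a [model_spec()] (or name string).
#' @param table feature table from [cohort_feature_table()].
#' @param split a [stratified_split()].
#' @param positive positive class. Default `"pCR"`.
#' @return List `X_train`, `y_train`, `X_test`, `y_test`, `columns`,
#'   `center`, `scale`, `dropped_columns`.
#' @export
build_design <- function(spec, table, split, positive = "pCR") {
  if (is.character(spec)) spec <- parse_model_name(spec)
  cols <- .spec_columns(spec, names(table))
  if (length(cols) == 0L)
    stop("model ", spec$name, " resolves to no feature columns")
  X <- as.matrix(table[, cols, drop = FALSE])
  y <- as.integer(.positive_indicator(table$response, positive))
  Xtr <- X[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xte <- X[split$test, , drop = FALSE]; yte <- y[split$test]
  keep_tr <- stats::complete.cases(Xtr)
  keep_te <- stats::complete.cases(Xte)
  Xtr <- Xtr[keep_tr, , drop = FALSE]; ytr <- ytr[keep_tr]
  Xte <- Xte[keep_te, , drop = FALSE]; yte <- yte[keep_te]
  if (nrow(Xtr) < 10L)
    stop("model ", spec$name, ": fewer than 10 complete training subjects")
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd)
  dropped <- colnames(Xtr)[scl == 0 | !is.finite(scl)]
  if (length(dropped))
    warning("model ", spec$name, ": dropping ", length(dropped),
            " zero-variance training column(s)")
  keep <- setdiff(colnames(Xtr), dropped)
  if (length(keep) == 0L)
    stop("model ", spec$name, ": all columns degenerate")
  Xtr <- scale(Xtr[, keep, drop = FALSE], ctr[keep], scl[keep])
  Xte <- scale(Xte[, keep, drop = FALSE], ctr[keep], scl[keep])
  list(X_train = Xtr, y_train = ytr, X_test = Xte, y_test = yte,
       columns = keep, center = ctr[keep], scale = scl[keep],
       dropped_columns = dropped, spec = spec)
}

.stratified_folds <- function(y, k, seed) {
  .with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Elastic-net logistic regression tuned by cross-validated AUC
#'
#' Grid search over mixing parameter `alpha` in `{0.1, ..., 1.0}` crossed
#' with a log-spaced penalty path (the glmnet path at each alpha). For
#' each pair the mean AUC over `k` stratified CV folds is computed from
#' held-out linear predictors; the pair maximizing mean CV AUC is
#' selected, ties broken toward the strongest penalty (largest lambda,
#' then largest alpha), and the model is refit on all training data at
#' the selected pair.
#'
#' @param X standardized design matrix (training subjects x features).
#' @param y binary 0/1 response.
#' @param seed integer seed controlling fold assignment.
#' @param alphas mixing-parameter grid. Default `seq(0.1, 1, by = 0.1)`.
#' @param nlambda penalty-path length per alpha. Default 50.
#' @param nfolds CV folds. Default 5 (reduced when a class is smaller).
#' @return A `fit_result`: list with `spec` (filled by the caller),
#'   `alpha`, `lambda`, `cv_mean_auc`, `intercept`, `coefficients`
#'   (nonzero only), `auc_train`, `ci_train`, `n_train`.
#' @export
fit_elastic_net_cv <- function(X, y, seed, alphas = seq(0.1, 1, by = 0.1),
                               nlambda = 50L, nfolds = 5L) {
  stopifnot(length(unique(y)) == 2L)
  nfolds <- min(nfolds, min(table(y)))
  if (nfolds < 2L) stop("too few subjects per class for cross-validation")
  fold <- .stratified_folds(y, nfolds, seed)
  best <- NULL
  for (alpha in alphas) {
    path <- tryCatch(
      glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                     nlambda = nlambda, standardize = FALSE),
      error = function(e) NULL)
    if (is.null(path) || length(path$lambda) == 0L) {
      warning("alpha = ", alpha, ": path failed; skipped")
      next
    }
    lambdas <- path$lambda
    auc_fold <- matrix(NA_real_, nrow = nfolds, ncol = length(lambdas))
    ok <- TRUE
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      fit_f <- tryCatch(
        glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                       alpha = alpha, lambda = lambdas,
                       standardize = FALSE),
        error = function(e) NULL)
      if (is.null(fit_f)) { ok <- FALSE; break }
      eta <- stats::predict(fit_f, X[!tr, , drop = FALSE], s = lambdas,
                            type = "link")
      yv <- y[!tr]
      auc_fold[f, ] <- apply(eta, 2, function(sc)
        if (stats::sd(sc) == 0) 0.5 else auc(sc, yv, positive = 1))
    }
    if (!ok) {
      warning("alpha = ", alpha, ": a CV fold failed; skipped")
      next
    }
    mean_auc <- colMeans(auc_fold)
    cand <- data.frame(alpha = alpha, lambda = lambdas, cv = mean_auc)
    best <- rbind(best, cand)
  }
  if (is.null(best)) stop("elastic-net tuning failed at every grid point")
  ord <- order(-best$cv, -best$lambda, -best$alpha)
  sel <- best[ord[1L], ]
  refit <- glmnet::glmnet(X, y, family = "binomial", alpha = sel$alpha,
                          nlambda = nlambda, standardize = FALSE)
  beta <- as.matrix(stats::predict(refit, s = sel$lambda,
                                   type = "coefficients"))[, 1L]
  coefs <- beta[-1L][beta[-1L] != 0]
  eta_tr <- as.numeric(beta[1L] + X %*% beta[-1L])
  a_tr <- if (stats::sd(eta_tr) == 0) 0.5 else auc(eta_tr, y, positive = 1)
  ci_tr <- auc_ci95(eta_tr, y, positive = 1)
  structure(list(spec = NULL, alpha = sel$alpha, lambda = sel$lambda,
                 cv_mean_auc = sel$cv, intercept = unname(beta[1L]),
                 coefficients = coefs, auc_train = a_tr, ci_train = ci_tr,
                 n_train = length(y), refit_path = refit),
            class = "fit_result")
}

#' Evaluate a fitted model on the held-out test design
#'
#' Scores test subjects with the fitted linear predictor and returns the
#' (raw, unoriented) test AUC with its DeLong 95% CI.
#'
#' @param fit a `fit_result` from [fit_elastic_net_cv()].
#' @param X_test standardized test design (training-set statistics).
#' @param y_test binary 0/1 response.
#' @return List `auc_test`, `ci_test`, `scores`.
#' @export
evaluate_model <- function(fit, X_test, y_test) {
  beta <- stats::setNames(rep(0, ncol(X_test)), colnames(X_test))
  beta[names(fit$coefficients)] <- fit$coefficients
  eta <- as.numeric(fit$intercept + X_test %*% beta)
  a <- if (stats::sd(eta) == 0) 0.5 else auc(eta, y_test, positive = 1)
  ci <- auc_ci95(eta, y_test, positive = 1)
  list(auc_test = a, ci_test = ci, scores = eta)
}

#' Fit and evaluate a suite of models
#'
#' Runs [build_design()], [fit_elastic_net_cv()] and [evaluate_model()]
#' for every spec, flags rows meeting the dual-cohort rule
#' (train AUC >= `threshold` and test AUC >= `threshold`), and records
#' per-spec failures without aborting the suite.
#'
#' @param specs list of [model_spec()]s / names; default the 20 published
#'   models from [default_model_suite()].
#' @param table feature table.
#' @param split a [stratified_split()].
#' @param seed integer seed (CV folds).
#' @param threshold dual-cohort AUC flag threshold. Default 0.75.
#' @param positive positive class. Default `"pCR"`.
#' @return `data.frame`: one row per spec with `model`, `n_features`,
#'   `n_nonzero`, `alpha`, `lambda`, `cv_mean_auc`, `auc_train`,
#'   `ci_train_lo/hi`, `auc_test`, `ci_test_lo/hi`, `flagged`, `error`.
#'   Fitted objects are attached as attribute `fits`.
#' @export
run_model_suite <- function(specs = default_model_suite(), table, split,
                            seed, threshold = 0.75, positive = "pCR") {
  fits <- vector("list", length(specs))
  rows <- lapply(seq_along(specs), function(i) {
    spec <- specs[[i]]
    if (is.character(spec)) spec <- parse_model_name(spec)
    out <- tryCatch({
      des <- build_design(spec, table, split, positive)
      fit <- fit_elastic_net_cv(des$X_train, des$y_train, seed = seed)
      fit$spec <- spec
      ev <- evaluate_model(fit, des$X_test, des$y_test)
      fits[[i]] <<- fit
      data.frame(model = spec$name, n_features = length(des$columns),
                 n_nonzero = length(fit$coefficients), alpha = fit$alpha,
                 lambda = fit$lambda, cv_mean_auc = fit$cv_mean_auc,
                 auc_train = fit$auc_train,
                 ci_train_lo = fit$ci_train[1], ci_train_hi = fit$ci_train[2],
                 auc_test = ev$auc_test,
                 ci_test_lo = ev$ci_test[1], ci_test_hi = ev$ci_test[2],
                 flagged = fit$auc_train >= threshold &&
                   ev$auc_test >= threshold,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(model = spec$name, n_features = NA_integer_,
                 n_nonzero = NA_integer_, alpha = NA_real_,
                 lambda = NA_real_, cv_mean_auc = NA_real_,
                 auc_train = NA_real_, ci_train_lo = NA_real_,
                 ci_train_hi = NA_real_, auc_test = NA_real_,
                 ci_test_lo = NA_real_, ci_test_hi = NA_real_,
                 flagged = FALSE, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "fits") <- fits
  res
}
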
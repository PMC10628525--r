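.timepoints <- c("BL", "C2", "C4")
.delta_pairs <- c("C2BL", "C4BL", "C4C2")
.blocks <- c(.timepoints,
             paste0("AD-", .delta_pairs), paste0("RD-", .delta_pairs))
.regions <- c(Peritumoral = "Peritumoral", Tumoral = "Tumor")

.check_matched_names <- function(f_late, f_early) {
  if (!identical(names(f_late), names(f_early))) {
    bad <- union(setdiff(names(f_late), names(f_early)),
                 setdiff(names(f_early), names(f_late)))
    stop("feature name mismatch: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "")
  }
}

#' Absolute difference of two feature vectors
#'
#' `AD = f_late - f_early` per feature; missing if either input is
#' missing. Names gain the prefix `AD-<pair>_`.
#'
#' @param f_late,f_early named numeric feature vectors with identical
#'   names (e.g. two time points of [extract_features()]).
#' @param pair label of the time-point pair, e.g. `"C4BL"`.
#' @return Named numeric vector.
#' @export
absolute_difference <- function(f_late, f_early, pair = "C4BL") {
  .check_matched_names(f_late, f_early)
  out <- as.numeric(f_late) - as.numeric(f_early)
  stats::setNames(out, paste0("AD-", pair, "_", names(f_late)))
}

#' Relative difference of two feature vectors
#'
#' `RD = (f_late - f_early) / |f_early|`, reported as a fraction. The
#' absolute-value denominator keeps the sign of RD aligned with the
#' direction of change even for negative-valued features (e.g. cluster
#' shade). `RD = 0` when both values are 0; missing when
#' `f_early = 0 != f_late` or when either input is missing.
#'
#' @inheritParams absolute_difference
#' @return Named numeric vector.
#' @export
relative_difference <- function(f_late, f_early, pair = "C4BL") {
  .check_matched_names(f_late, f_early)
  late <- as.numeric(f_late); early <- as.numeric(f_early)
  out <- (late - early) / abs(early)
  out[early == 0 & late == 0] <- 0
  out[early == 0 & late != 0] <- NA_real_
  stats::setNames(out, paste0("RD-", pair, "_", names(f_late)))
}

# per-region per-subject block of 9 x 310 named features, paper naming
.subject_region_row <- function(per_tp, region_prefix) {
  ad <- list(
    absolute_difference(per_tp$C2, per_tp$BL, "C2BL"),
    absolute_difference(per_tp$C4, per_tp$BL, "C4BL"),
    absolute_difference(per_tp$C4, per_tp$C2, "C4C2"))
  rd <- list(
    relative_difference(per_tp$C2, per_tp$BL, "C2BL"),
    relative_difference(per_tp$C4, per_tp$BL, "C4BL"),
    relative_difference(per_tp$C4, per_tp$C2, "C4C2"))
  plain <- lapply(.timepoints, function(tp)
    stats::setNames(as.numeric(per_tp[[tp]]),
                    paste0(tp, "_", names(per_tp[[tp]]))))
  v <- c(unlist(plain), unlist(ad), unlist(rd))
  stats::setNames(v, paste0(region_prefix, "_DCE_", names(v)))
}

#' Assemble the wide longitudinal feature table
#'
#' Builds one row per subject over
#' `{Peritumoral, Tumor} x {BL, C2, C4, AD-*, RD-*} x 310` features
#' (2790 columns per region) using the naming scheme
#' `<Region>_DCE_<Block>_<FO|GLCM>_<Name>`, e.g.
#' `Peritumoral_DCE_RD-C4BL_FO_Percentile.95`, and attaches the response
#' label. Note the asymmetry of the published convention: feature columns
#' use the region prefix `Tumor`, model names (see [model_spec()]) use
#' the token `Tumoral`.
#'
#' @param features nested list: `features[[subject]][[region]][[tp]]` is
#'   a 310-feature vector, regions `Peritumoral`/`Tumoral`, time points
#'   `BL`/`C2`/`C4`.
#' @param subject_ids character vector of subject IDs.
#' @param labels response labels (`"pCR"` / `"non-pCR"`) per subject.
#' @param gray_levels gray-level counts the features were extracted with
#'   (sets the expected column set). Default `c(8, 16, 32, 64, 256)`.
#' @return `data.frame` with columns `subject_id`, `response`, then the
#'   feature columns (checked names; `check.names = FALSE`).
#' @export
assemble_longitudinal_table <- function(features, subject_ids, labels,
                                        gray_levels = .default_gray_levels) {
  stopifnot(length(features) == length(subject_ids),
            length(labels) == length(subject_ids))
  nms <- feature_names(gray_levels)
  nfeat <- length(nms)
  header <- as.vector(vapply(names(.regions), function(rg)
    paste0(.regions[[rg]], "_DCE_",
           as.vector(vapply(.blocks, function(b)
             paste0(b, "_", nms), character(nfeat)))),
    character(9L * length(nms))))
  if (length(features) == 0L) {
    tab <- as.data.frame(matrix(numeric(0), nrow = 0,
                                ncol = length(header) + 2L))
    names(tab) <- c("subject_id", "response", header)
    return(tab)
  }
  rows <- lapply(seq_along(features), function(s) {
    per_region <- features[[s]]
    row <- unlist(lapply(names(.regions), function(rg) {
      per_tp <- per_region[[rg]]
      if (is.null(per_tp)) {
        warning("subject ", subject_ids[s], ": region ", rg,
                " missing; columns set to NA")
        return(stats::setNames(
          rep(NA_real_, 9L * nfeat),
          paste0(.regions[[rg]], "_DCE_",
                 as.vector(vapply(.blocks, function(b)
                   paste0(b, "_", nms), character(nfeat))))))
      }
      .subject_region_row(per_tp, .regions[[rg]])
    }))
    row
  })
  mat <- do.call(rbind, rows)
  stopifnot(identical(colnames(mat), header))
  tab <- data.frame(subject_id = subject_ids, response = labels,
                    check.names = FALSE, stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(mat, check.names = FALSE,
                                  row.names = NULL))
  tab
}

#' Extract per-subject, per-region, per-time-point features for a cohort
#'
#' Runs tumor + peritumoral feature extraction at all three time points
#' for every subject and returns the nested structure
#' [assemble_longitudinal_table()] consumes. The peritumoral region is a
#' ring of `thickness_mm` around the (tumor or tumor-bed) mask.
#'
#' @param cohort list of `subject_record`s.
#' @param thickness_mm peritumoral ring thickness (mm). Default 10.
#' @param gray_levels gray-level counts for GLCM features.
#' @param masks optional override: function(record, tp) returning the
#'   tumor [roi_mask()] to use (e.g. second-reader masks); default uses
#'   the record's own masks.
#' @return Nested list of feature vectors.
#' @export
extract_cohort_features <- function(cohort, thickness_mm = 10,
                                    gray_levels = .default_gray_levels,
                                    masks = NULL) {
  lapply(cohort, function(rec) {
    per_region <- list(Peritumoral = list(), Tumoral = list())
    for (tp in .timepoints) {
      tpdat <- rec$timepoints[[tp]]
      tumor <- if (is.null(masks)) tpdat$mask else masks(rec, tp)
      ring <- if (sum(tumor$data) > 0)
        peritumoral_ring(tumor, thickness_mm = thickness_mm)
      else {
        warning("subject ", rec$subject_id, " ", tp,
                ": empty tumor mask; empty ring")
        roi_mask(array(0L, dim = dim(tumor$data)), spacing = tumor$spacing)
      }
      per_region$Tumoral[[tp]] <-
        suppressWarnings(extract_features(tpdat$volume, tumor, gray_levels))
      per_region$Peritumoral[[tp]] <-
        suppressWarnings(extract_features(tpdat$volume, ring, gray_levels))
    }
    per_region
  })
}

#' Build the full longitudinal feature table for a cohort in one call
#'
#' Convenience wrapper: [extract_cohort_features()] then
#' [assemble_longitudinal_table()].
#'
#' @inheritParams extract_cohort_features
#' @return The wide feature `data.frame`.
#' @export
cohort_feature_table <- function(cohort, thickness_mm = 10,
                                 gray_levels = .default_gray_levels,
                                 masks = NULL) {
  feats <- extract_cohort_features(cohort, thickness_mm, gray_levels, masks)
  assemble_longitudinal_table(
    feats,
    vapply(cohort, function(r) r$subject_id, character(1)),
    vapply(cohort, function(r) r$response, character(1)),
    gray_levels = gray_levels)
}
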
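#' @useDynLib deltaradiomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.fo_names <- c("Minimum", "Maximum", "Mean", "Standard.Deviation",
               "Percentile.1", "Percentile.5", "Percentile.95",
               "Percentile.99", "Skewness", "Kurtosis")

.glcm_scalar_names <- c("Autocorrelation", "Correlation", "Contrast",
                        "Cluster.Prominence", "Cluster.Shade",
                        "Dissimilarity", "Energy", "Entropy", "Homogeneity",
                        "Maximum.Probability", "Sum.of.Squares.Variance",
                        "Sum.Average", "Sum.Variance", "Sum.Entropy",
                        "Difference.Variance", "Difference.Entropy",
                        "IMC1", "IMC2", "IDN", "IDMN")

.glcm_aggregates <- c("Mean", "Range", "Angular.Variance")

.default_gray_levels <- c(8L, 16L, 32L, 64L, 256L)

#' The 13 canonical 3D GLCM offset directions
#'
#' Unique voxel offsets at Chebyshev distance 1 (26-connectivity modulo
#' sign; the co-occurrence matrix is accumulated symmetrically so a
#' direction and its negation are identical). This is the standard
#' direction set for volumetric texture and is closed under 90-degree
#' axis rotations, which is what makes the mean/range/angular-variance
#' aggregates rotation invariant on isotropic grids.
#'
#' @return 13 x 3 integer matrix, one offset per row.
#' @export
glcm_offsets <- function() {
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  o <- o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ]
  keep <- o$dx > 0 | (o$dx == 0 & o$dy > 0) | (o$dx == 0 & o$dy == 0 & o$dz > 0)
  m <- as.matrix(o[keep, ])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Gray-level quantization of in-ROI intensities
#'
#' Equal-width binning of the in-ROI intensity range `[min, max]` into
#' `n_levels` bins; the maximum maps to `n_levels`, and a constant ROI
#' maps every voxel to level 1.
#'
#' @param intensities numeric vector of in-ROI intensities (>= 1 value).
#' @param n_levels integer >= 2.
#' @return Integer vector of levels in `1..n_levels`.
#' @export
quantize_roi <- function(intensities, n_levels) {
  if (length(intensities) == 0L) stop("quantize_roi: empty ROI")
  stopifnot(n_levels >= 2L)
  lo <- min(intensities); hi <- max(intensities)
  if (hi == lo) return(rep(1L, length(intensities)))
  lev <- floor((intensities - lo) / (hi - lo) * n_levels) + 1L
  as.integer(pmin(lev, n_levels))
}

#' First-order histogram features
#'
#' The 10 first-order statistics of the raw (unquantized) in-ROI
#' intensities: minimum; maximum; mean; standard deviation (n-1);
#' 1st, 5th, 95th and 99th percentiles (linear interpolation between
#' order statistics); adjusted Fisher-Pearson skewness; Pearson kurtosis
#' (normal = 3). An empty ROI yields all-missing; a singleton ROI leaves
#' SD, skewness and kurtosis missing.
#'
#' @param intensities numeric vector of in-ROI intensities.
#' @return Named numeric vector of length 10 (names `FO_<Name>`).
#' @export
first_order_features <- function(intensities) {
  out <- stats::setNames(rep(NA_real_, 10L), paste0("FO_", .fo_names))
  x <- intensities[is.finite(intensities)]
  n <- length(x)
  if (n == 0L) return(out)
  qs <- stats::quantile(x, c(0.01, 0.05, 0.95, 0.99), names = FALSE, type = 7)
  out["FO_Minimum"] <- min(x)
  out["FO_Maximum"] <- max(x)
  out["FO_Mean"] <- mean(x)
  out["FO_Percentile.1"] <- qs[1]
  out["FO_Percentile.5"] <- qs[2]
  out["FO_Percentile.95"] <- qs[3]
  out["FO_Percentile.99"] <- qs[4]
  if (n >= 2L) {
    s <- stats::sd(x)
    out["FO_Standard.Deviation"] <- s
    m <- mean(x)
    m2 <- mean((x - m)^2)
    if (m2 > 0) {
      g1 <- mean((x - m)^3) / m2^1.5
      out["FO_Skewness"] <- if (n > 2L) g1 * sqrt(n * (n - 1)) / (n - 2) else NA_real_
      out["FO_Kurtosis"] <- mean((x - m)^4) / m2^2
    } else {
      out["FO_Skewness"] <- NA_real_
      out["FO_Kurtosis"] <- NA_real_
    }
  }
  out
}

#' Gray-level co-occurrence matrix for one offset
#'
#' Counts in-ROI voxel pairs `(v, v + offset)` where both ends lie inside
#' the mask, accumulates symmetrically (each pair increments `(i, j)` and
#' `(j, i)`), and normalizes to sum 1. If the offset admits no valid
#' in-mask pair the matrix is flagged empty and downstream scalars for
#' that direction are missing.
#'
#' @param levels integer 3D array of quantized levels (`1..n_levels`
#'   inside the ROI, 0 outside).
#' @param mask binary 3D array / [roi_mask()]; pairs must have both ends
#'   in the mask. May be `NULL` if `levels` is already 0 outside the ROI.
#' @param offset integer length-3 voxel offset (one of [glcm_offsets()]).
#' @param n_levels number of gray levels.
#' @return `n_levels x n_levels` probability matrix with attribute
#'   `empty` (TRUE when no valid pair exists).
#' @export
glcm_matrix <- function(levels, mask = NULL, offset, n_levels) {
  lv <- levels
  if (!is.null(mask)) {
    m <- mask_data(mask)
    lv <- lv * (m != 0)
  }
  storage.mode(lv) <- "integer"
  cnt <- .glcm_counts_cpp(lv, dim(lv), as.integer(offset), as.integer(n_levels))
  s <- sum(cnt)
  if (s == 0) {
    attr(cnt, "empty") <- TRUE
    return(cnt)
  }
  P <- cnt / s
  attr(P, "empty") <- FALSE
  P
}

.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Haralick-family scalar features of one GLCM
#'
#' Computes the 20 co-occurrence scalars used per direction and gray
#' level: autocorrelation, correlation, contrast, cluster prominence,
#' cluster shade, dissimilarity, energy, entropy, homogeneity, maximum
#' probability, sum of squares (variance), sum average, sum variance, sum
#' entropy, difference variance, difference entropy, the two information
#' measures of correlation, and the normalized inverse difference and
#' inverse difference moment. Entropies are base 2 with the convention
#' `0 log 0 = 0`; correlation (and IMC1) are missing for a degenerate
#' (zero marginal SD) matrix.
#'
#' @param P normalized symmetric GLCM from [glcm_matrix()].
#' @return Named numeric vector of length 20.
#' @export
glcm_scalar_features <- function(P) {
  out <- stats::setNames(rep(NA_real_, 20L), .glcm_scalar_names)
  if (isTRUE(attr(P, "empty"))) return(out)
  ng <- nrow(P)
  # work on the nonzero entries only: GLCMs of modest ROIs are sparse
  nz <- which(P > 0)
  p <- P[nz]
  i <- ((nz - 1L) %% ng) + 1L
  j <- ((nz - 1L) %/% ng) + 1L
  px <- numeric(ng)                       # row marginal (= column, symmetric)
  rs <- rowsum(p, i)
  px[as.integer(rownames(rs))] <- rs
  lev <- seq_len(ng)
  mu <- sum(lev * px)
  s2 <- sum((lev - mu)^2 * px)

  out["Autocorrelation"] <- sum(i * j * p)
  out["Contrast"] <- sum((i - j)^2 * p)
  out["Cluster.Prominence"] <- sum((i + j - 2 * mu)^4 * p)
  out["Cluster.Shade"] <- sum((i + j - 2 * mu)^3 * p)
  out["Dissimilarity"] <- sum(abs(i - j) * p)
  out["Energy"] <- sum(p^2)
  out["Entropy"] <- .entropy2(p)
  out["Homogeneity"] <- sum(p / (1 + (i - j)^2))
  out["Maximum.Probability"] <- max(p)
  out["Sum.of.Squares.Variance"] <- sum((i - mu)^2 * p)
  out["IDN"] <- sum(p / (1 + abs(i - j) / ng))
  out["IDMN"] <- sum(p / (1 + (i - j)^2 / ng^2))
  if (s2 > 0)
    out["Correlation"] <- (sum(i * j * p) - mu^2) / s2

  # sum / difference marginals p_{x+y}, p_{x-y}
  ss <- rowsum(p, i + j)
  ks <- as.integer(rownames(ss))
  ps <- as.vector(ss)
  sa <- sum(ks * ps)
  out["Sum.Average"] <- sa
  out["Sum.Variance"] <- sum((ks - sa)^2 * ps)
  out["Sum.Entropy"] <- .entropy2(ps)
  dd <- rowsum(p, abs(i - j))
  kd <- as.integer(rownames(dd))
  pd <- as.vector(dd)
  mud <- sum(kd * pd)
  out["Difference.Variance"] <- sum((kd - mud)^2 * pd)
  out["Difference.Entropy"] <- .entropy2(pd)

  # information measures of correlation
  hxy <- out[["Entropy"]]
  hx <- .entropy2(px)
  ppij <- px[i] * px[j]
  hxy1 <- -sum(p[ppij > 0] * log2(ppij[ppij > 0]))
  pxp <- px[px > 0]
  hxy2 <- .entropy2(outer(pxp, pxp))
  if (hx > 0)
    out["IMC1"] <- (hxy - hxy1) / hx
  out["IMC2"] <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  out
}

#' Rotation-invariant aggregation of a per-direction scalar
#'
#' Collapses the 13 per-direction values of one GLCM scalar into the
#' mean, range (max - min), and angular variance (population variance
#' across directions). Missing directions are excluded; if every
#' direction is missing all three aggregates are missing.
#'
#' @param per_direction numeric vector of one scalar across directions.
#' @return Named numeric vector `c(Mean, Range, Angular.Variance)`.
#' @export
rotation_invariant_aggregate <- function(per_direction) {
  v <- per_direction[!is.na(per_direction)]
  if (length(v) == 0L)
    return(stats::setNames(rep(NA_real_, 3L), .glcm_aggregates))
  stats::setNames(c(mean(v), max(v) - min(v), mean((v - mean(v))^2)),
                  .glcm_aggregates)
}

#' Names of the 310-feature set
#'
#' @param gray_levels gray-level counts for the GLCM families.
#' @return Character vector: 10 `FO_*` names followed by
#'   `GLCM_<Scalar>.<Aggregate>.N<levels>` names.
#' @export
feature_names <- function(gray_levels = .default_gray_levels) {
  glcm <- as.vector(vapply(gray_levels, function(lv)
    as.vector(vapply(.glcm_scalar_names, function(s)
      paste0("GLCM_", s, ".", .glcm_aggregates, ".N", lv),
      character(3))), character(60L)))
  c(paste0("FO_", .fo_names), glcm)
}

# crop volume+mask arrays to the mask bounding box (plus nothing: GLCM
# pairs need both ends in-mask, so context outside the box is irrelevant)
.crop_to_mask <- function(vol, m) {
  idx <- which(m != 0, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  list(vol = vol[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                 rng[1, 3]:rng[2, 3], drop = FALSE],
       mask = m[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                rng[1, 3]:rng[2, 3], drop = FALSE])
}

#' Extract the full 310-feature vector from a masked volume
#'
#' 10 first-order features of the raw in-ROI intensities plus, for each
#' gray-level count (default 8, 16, 32, 64, 256), the 20 GLCM scalars
#' aggregated over the 13 directions into mean, range and angular
#' variance (60 per level, 300 total). An empty mask yields 310 missing
#' values with a warning.
#'
#' @param volume an [image_volume()] or 3D array.
#' @param mask an [roi_mask()] or binary 3D array on the same grid.
#' @param gray_levels gray-level counts. Default `c(8, 16, 32, 64, 256)`.
#' @return Named numeric vector of length `10 + 60 * length(gray_levels)`
#'   with attributes `n_voxels` and `conventions`.
#' @examples
#' v <- array(stats::rnorm(16^3), dim = c(16, 16, 16))
#' m <- array(0L, dim = dim(v)); m[5:12, 5:12, 5:12] <- 1L
#' f <- extract_features(v, m)
#' length(f)  # 310
#' @export
extract_features <- function(volume, mask,
                             gray_levels = .default_gray_levels) {
  vol <- if (inherits(volume, "image_volume")) volume$data else volume
  m <- mask_data(mask)
  if (!identical(dim(vol), dim(m)))
    stop("volume and mask are on different grids")
  nm <- feature_names(gray_levels)
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  nvox <- sum(m != 0)
  attr(out, "n_voxels") <- nvox
  attr(out, "conventions") <-
    "glcm3d;13dir;equal-width-minmax;log2;sd(n-1);quantile-type7;kurtosis-pearson"
  if (nvox == 0L) {
    warning("extract_features: empty mask; all 310 features missing")
    return(out)
  }
  cr <- .crop_to_mask(vol, m)
  inmask <- cr$mask != 0
  vals <- cr$vol[inmask]
  out[1:10] <- first_order_features(vals)
  offs <- glcm_offsets()
  for (lv in gray_levels) {
    q <- array(0L, dim = dim(cr$mask))
    q[inmask] <- quantize_roi(vals, lv)
    scal <- matrix(NA_real_, nrow = 20L, ncol = nrow(offs))
    for (d in seq_len(nrow(offs))) {
      P <- glcm_matrix(q, mask = NULL, offset = offs[d, ], n_levels = lv)
      scal[, d] <- glcm_scalar_features(P)
    }
    for (s in seq_len(20L)) {
      agg <- rotation_invariant_aggregate(scal[s, ])
      out[paste0("GLCM_", .glcm_scalar_names[s], ".", .glcm_aggregates,
                 ".N", lv)] <- agg
    }
  }
  out
}
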
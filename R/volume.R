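#' Image volume and ROI mask containers
#'
#' `image_volume()` wraps a 3D numeric array together with its physical
#' voxel spacing (mm) and origin, the minimal geometry needed by the
#' pipeline (early-phase DCE subtraction images are plain scalar volumes).
#' `roi_mask()` wraps a binary 3D array on the same grid.
#'
#' @param data 3D numeric array of finite intensities (signal units).
#' @param spacing numeric length-3, voxel edge lengths in mm, all > 0.
#' @param origin numeric length-3, mm. Default `c(0, 0, 0)`.
#' @return An object of class `image_volume` (list with `data`, `spacing`,
#'   `origin`).
#' @examples
#' v <- image_volume(array(rnorm(8^3), dim = c(8, 8, 8)), spacing = c(1, 1, 3))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 8L))
    stop("volume must have at least 8 voxels per axis; got ",
         paste(dim(data), collapse = "x"))
  if (!all(is.finite(data))) stop("all intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @param volume the `image_volume` the mask annotates (used to check the
#'   grid); may be `NULL` when the mask is free-standing.
#' @rdname image_volume
#' @export
roi_mask <- function(data, spacing = c(1, 1, 1), volume = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask `data` must be a 3D array")
  if (!all(data %in% c(0, 1)))
    stop("mask values must be 0 or 1")
  if (!is.null(volume)) {
    if (!identical(dim(data), dim(volume$data)))
      stop("mask shape ", paste(dim(data), collapse = "x"),
           " does not match volume shape ",
           paste(dim(volume$data), collapse = "x"))
    spacing <- volume$spacing
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  structure(list(data = array(as.integer(data), dim = dim(data)),
                 spacing = spacing),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " in mask\n", sep = "")
  invisible(x)
}

mask_data <- function(mask) {
  if (inherits(mask, "roi_mask")) mask$data else mask
}
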
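#' Configuration for the synthetic longitudinal cohort generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' a cohort of pCR / non-pCR subjects, each with a roughly ellipsoidal
#' enhancing tumor on an early-phase DCE subtraction volume at three time
#' points (BL, C2, C4). Tumor radius and mean enhancement both shrink by
#' class-specific per-time-point decay factors, so responders de-enhance
#' faster; a low-enhancement peritumoral shell surrounds the tumor;
#' spatial texture comes from Gaussian-smoothed white noise; second-reader
#' and repeat segmentations are simulated by bounded boundary jitter.
#'
#' Defaults state the emulated world: 78 pCR / 85 non-pCR subjects,
#' ~1 x 1 x 3 mm voxels (in-plane vs slice resolution of a typical breast
#' DCE protocol), tumor semi-axes 6-12 mm (1.2-2.4 cm diameters, the size
#' range of the example lesions), strong C4 de-enhancement for pCR
#' (factor 0.15) versus mild for non-pCR (0.75).
#'
#' @param n_pcr,n_nonpcr subjects per response class (>= 1).
#' @param image_shape integer length-3 grid shape.
#' @param spacing_mm voxel spacing, mm.
#' @param tumor_radius_range_mm range the three BL ellipsoid semi-axes are
#'   drawn from (mm).
#' @param enhancement_bl mean tumor enhancement at BL (signal units).
#' @param decline_pcr,decline_nonpcr length-3 multiplicative decay factors
#'   for (BL, C2, C4), each in (0, 1.5]; applied to both the tumor
#'   semi-axes and the enhancement.
#' @param noise_sd additive Gaussian noise SD (signal units), >= 0.
#' @param texture_corr_length_mm Gaussian smoothing scale that creates
#'   spatial texture (mm).
#' @param reader_perturb_mm boundary jitter magnitude for the simulated
#'   second reader (mm); the reader-1 repeat uses half this magnitude.
#' @param seed integer master seed; the whole cohort is a pure function of
#'   the config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_pcr = 78L, n_nonpcr = 85L,
                          image_shape = c(40L, 40L, 16L),
                          spacing_mm = c(1, 1, 3),
                          tumor_radius_range_mm = c(6, 12),
                          enhancement_bl = 100,
                          decline_pcr = c(1, 0.55, 0.15),
                          decline_nonpcr = c(1, 0.9, 0.75),
                          noise_sd = 5,
                          texture_corr_length_mm = 3,
                          reader_perturb_mm = 1,
                          seed = 1L) {
  stopifnot(n_pcr >= 1L, n_nonpcr >= 1L,
            length(image_shape) == 3L, all(image_shape >= 8L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(tumor_radius_range_mm) == 2L,
            tumor_radius_range_mm[1] > 0,
            diff(tumor_radius_range_mm) >= 0,
            enhancement_bl > 0,
            length(decline_pcr) == 3L, length(decline_nonpcr) == 3L,
            all(decline_pcr >= 0), all(decline_pcr <= 1.5),
            all(decline_nonpcr >= 0), all(decline_nonpcr <= 1.5),
            noise_sd >= 0, texture_corr_length_mm > 0,
            reader_perturb_mm >= 0)
  structure(list(
    n_pcr = as.integer(n_pcr), n_nonpcr = as.integer(n_nonpcr),
    image_shape = as.integer(image_shape), spacing_mm = as.numeric(spacing_mm),
    tumor_radius_range_mm = as.numeric(tumor_radius_range_mm),
    enhancement_bl = enhancement_bl,
    decline_pcr = as.numeric(decline_pcr),
    decline_nonpcr = as.numeric(decline_nonpcr),
    noise_sd = noise_sd, texture_corr_length_mm = texture_corr_length_mm,
    reader_perturb_mm = reader_perturb_mm, seed = as.integer(seed)
  ), class = "cohort_config")
}

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# deterministic per-subject seed (Lehmer-style mix, exact in doubles)
.derive_seed <- function(master, index) {
  as.integer((abs(as.numeric(master)) %% 2147483647 * 48271 +
                as.numeric(index) * 9973) %% 2147483647)
}

# separable Gaussian smoothing with physical sigma (mm); edge replication
.gauss_smooth <- function(arr, sigma_mm, spacing) {
  for (ax in 1:3) {
    sig_vox <- sigma_mm / spacing[ax]
    r <- max(1L, ceiling(3 * sig_vox))
    w <- exp(-0.5 * ((-r):r / sig_vox)^2)
    w <- w / sum(w)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    out <- matrix(0, nrow = d[1], ncol = ncol(m))
    idx <- seq_len(d[1])
    for (k in (-r):r) {
      src <- pmin(pmax(idx + k, 1L), d[1])
      out <- out + w[k + r + 1L] * m[src, , drop = FALSE]
    }
    arr <- aperm(array(out, dim = d), order(perm))
  }
  arr
}

# physical voxel-centre coordinates along each axis (mm)
.axis_coords <- function(shape, spacing) {
  lapply(1:3, function(ax) (seq_len(shape[ax]) - 0.5) * spacing[ax])
}

# binary ellipsoid indicator on the grid; semi_axes in mm, centre in mm
.ellipsoid_mask <- function(shape, spacing, centre, semi_axes) {
  co <- .axis_coords(shape, spacing)
  u2 <- lapply(1:3, function(ax) ((co[[ax]] - centre[ax]) / semi_axes[ax])^2)
  q <- outer(outer(u2[[1]], u2[[2]], `+`), u2[[3]], `+`)
  array(as.integer(q <= 1), dim = shape)
}

#' Generate one synthetic longitudinal subject
#'
#' Deterministic given `(config, response, subject_seed)`. The tumor is an
#' axis-aligned ellipsoid; at each time point its semi-axes and its mean
#' enhancement are the BL values times the class decay factor. Intensities
#' are enhancement x smoothed spatial texture plus Gaussian noise; the
#' tumor mask is the set of voxels inside the shrunken ellipsoid. A time
#' point whose enhancing region is empty gets a "tumor bed" mask equal to
#' the previous time point's mask (flagged `tumor_bed = TRUE`), modelling
#' segmentation of the tumor bed when no enhancement remains.
#'
#' @param config a [cohort_config()].
#' @param response `"pCR"` or `"non-pCR"`.
#' @param subject_seed integer seed for this subject.
#' @param subject_id subject identifier string.
#' @return A `subject_record`: list with `subject_id`, `response`,
#'   `timepoints` (named list BL/C2/C4 of `volume`, `mask`, `tumor_bed`),
#'   and `reader2_masks`, `reader1_repeat_masks` (same time-point names)
#'   when `reader_perturb_mm > 0`.
#' @export
generate_subject <- function(config, response, subject_seed,
                             subject_id = sprintf("S%05d", subject_seed %% 1e5)) {
  stopifnot(inherits(config, "cohort_config"))
  response <- match.arg(response, c("pCR", "non-pCR"))
  decay <- if (response == "pCR") config$decline_pcr else config$decline_nonpcr
  shape <- config$image_shape
  sp <- config$spacing_mm
  extent <- shape * sp

  .with_seed(subject_seed, {
    r0 <- stats::runif(3, config$tumor_radius_range_mm[1],
                       config$tumor_radius_range_mm[2])
    too_big <- which(2 * r0 >= extent)
    if (length(too_big))
      stop("tumor diameter ", round(2 * r0[too_big[1]], 1),
           " mm exceeds image extent along dimension ", too_big[1],
           " (", extent[too_big[1]], " mm)")
    jitter_room <- pmax((extent - 2 * r0) / 2 - sp, 0)
    centre <- extent / 2 + stats::runif(3, -1, 1) * pmin(jitter_room, 2)

    tex <- array(stats::rnorm(prod(shape)), dim = shape)
    tex <- .gauss_smooth(tex, config$texture_corr_length_mm, sp)
    tex <- (tex - mean(tex)) / stats::sd(tex)
    tex <- pmax(1 + 0.3 * tex, 0.05)  # multiplicative texture, CV ~0.3

    tps <- c("BL", "C2", "C4")
    timepoints <- vector("list", 3L)
    names(timepoints) <- tps
    prev_mask <- NULL
    for (t in 1:3) {
      f <- decay[t]
      tum <- if (f > 0)
        .ellipsoid_mask(shape, sp, centre, r0 * f)
      else
        array(0L, dim = shape)
      shell <- if (f > 0) {
        s <- .ellipsoid_mask(shape, sp, centre, r0 * f + 10)
        s * (1L - tum)
      } else array(0L, dim = shape)
      bg <- 1L - pmin(tum + shell, 1L)
      signal <- (2 * bg + config$enhancement_bl * f * tum +
                   0.3 * config$enhancement_bl * f * shell) * tex
      if (config$noise_sd > 0)
        signal <- signal + stats::rnorm(prod(shape), 0, config$noise_sd)
      vol <- image_volume(signal, spacing = sp)
      tumor_bed <- FALSE
      if (sum(tum) == 0L) {
        if (!is.null(prev_mask) && sum(prev_mask) > 0L) {
          tum <- prev_mask
          tumor_bed <- TRUE
        } else if (t == 1L) {
          stop("BL tumor mask is empty (decline_",
               if (response == "pCR") "pcr" else "nonpcr",
               " BL factor too small for the grid)")
        } else {
          tumor_bed <- TRUE
        }
      }
      timepoints[[t]] <- list(volume = vol,
                              mask = roi_mask(tum, spacing = sp),
                              tumor_bed = tumor_bed)
      prev_mask <- tum
    }

    rec <- list(subject_id = subject_id, response = response,
                timepoints = timepoints,
                reader2_masks = NULL, reader1_repeat_masks = NULL)
    if (config$reader_perturb_mm > 0) {
      rec$reader2_masks <- lapply(seq_along(tps), function(t)
        perturb_mask(timepoints[[t]]$mask, sp, config$reader_perturb_mm,
                     seed = .derive_seed(subject_seed, 1000 + t)))
      rec$reader1_repeat_masks <- lapply(seq_along(tps), function(t)
        perturb_mask(timepoints[[t]]$mask, sp, config$reader_perturb_mm / 2,
                     seed = .derive_seed(subject_seed, 2000 + t)))
      names(rec$reader2_masks) <- tps
      names(rec$reader1_repeat_masks) <- tps
    }
    structure(rec, class = "subject_record")
  })
}

#' Generate a full synthetic cohort
#'
#' Produces `n_pcr + n_nonpcr` subjects (pCR first), with per-subject
#' seeds derived deterministically from `config$seed`, so two runs with
#' the same config are identical.
#'
#' @param config a [cohort_config()].
#' @return List of `subject_record`s with a `labels` attribute.
#' @examples
#' cfg <- cohort_config(n_pcr = 2, n_nonpcr = 2, seed = 7)
#' cohort <- generate_cohort(cfg)
#' vapply(cohort, function(s) s$response, character(1))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_pcr + config$n_nonpcr
  labels <- c(rep("pCR", config$n_pcr), rep("non-pCR", config$n_nonpcr))
  cohort <- lapply(seq_len(n), function(i)
    generate_subject(config, labels[i], .derive_seed(config$seed, i),
                     subject_id = sprintf("S%04d", i)))
  attr(cohort, "labels") <- labels
  cohort
}

#' Perturb a mask boundary by a bounded physical magnitude
#'
#' Simulates an independent reader's segmentation: the returned mask
#' differs from the input only inside a shell of physical width
#' `magnitude_mm` around the input boundary. Implemented by thresholding
#' the signed centre-to-centre distance field at a smooth random level
#' field scaled to `[-magnitude_mm, magnitude_mm]`.
#'
#' @param mask an [roi_mask()] or binary array.
#' @param spacing voxel spacing (mm).
#' @param magnitude_mm maximum boundary displacement (mm), >= 0; 0 returns
#'   the input unchanged.
#' @param seed integer seed.
#' @return an [roi_mask()].
#' @export
perturb_mask <- function(mask, spacing = NULL, magnitude_mm, seed) {
  m <- mask_data(mask)
  if (is.null(spacing)) {
    spacing <- if (inherits(mask, "roi_mask")) mask$spacing else c(1, 1, 1)
  }
  stopifnot(magnitude_mm >= 0)
  if (sum(m != 0) == 0L) {
    warning("perturb_mask: empty input mask returned unchanged")
    return(roi_mask(m, spacing = spacing))
  }
  if (magnitude_mm == 0 || sum(m == 0) == 0L)
    return(roi_mask(m, spacing = spacing))
  d_out <- distance_from_mask(m, spacing)          # 0 inside
  d_in <- distance_from_mask(1L - m, spacing)      # 0 outside
  signed <- d_out - d_in                           # <0 inside, >0 outside
  .with_seed(seed, {
    lev <- array(stats::rnorm(prod(dim(m))), dim = dim(m))
    lev <- .gauss_smooth(lev, 2 * max(spacing), spacing)
    # typical displacement ~ magnitude/2, hard-clipped at the magnitude
    lev <- lev / stats::sd(lev) * (magnitude_mm / 2)
    lev <- pmin(pmax(lev, -magnitude_mm), magnitude_mm)
    out <- array(as.integer(signed <= lev), dim = dim(m))
    roi_mask(out, spacing = spacing)
  })
}

#' Write a cohort to disk as NIfTI volumes plus a manifest CSV
#'
#' @param cohort list of `subject_record`s from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Path of the manifest CSV (`manifest.csv` in `dir`), whose
#'   columns are `subject_id`, `response`, and per-time-point paths
#'   `vol_<tp>`, `mask_<tp>`, plus `reader2_mask_<tp>` /
#'   `repeat_mask_<tp>` when present.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tps <- c("BL", "C2", "C4")
  rows <- lapply(cohort, function(rec) {
    row <- list(subject_id = rec$subject_id, response = rec$response)
    for (tp in tps) {
      vp <- file.path(dir, sprintf("%s_%s_vol.nii.gz", rec$subject_id, tp))
      mp <- file.path(dir, sprintf("%s_%s_mask.nii.gz", rec$subject_id, tp))
      nifti_write(rec$timepoints[[tp]]$volume, vp)
      nifti_write(rec$timepoints[[tp]]$mask, mp)
      row[[paste0("vol_", tp)]] <- basename(vp)
      row[[paste0("mask_", tp)]] <- basename(mp)
      if (!is.null(rec$reader2_masks)) {
        rp <- file.path(dir, sprintf("%s_%s_mask_r2.nii.gz", rec$subject_id, tp))
        nifti_write(rec$reader2_masks[[tp]], rp)
        row[[paste0("reader2_mask_", tp)]] <- basename(rp)
      }
      if (!is.null(rec$reader1_repeat_masks)) {
        rp <- file.path(dir, sprintf("%s_%s_mask_r1rep.nii.gz", rec$subject_id, tp))
        nifti_write(rec$reader1_repeat_masks[[tp]], rp)
        row[[paste0("repeat_mask_", tp)]] <- basename(rp)
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  path
}

#' Read a cohort back from a manifest CSV written by [write_cohort()]
#'
#' @param manifest_path path to `manifest.csv`; volume/mask paths are
#'   resolved relative to its directory.
#' @return List of `subject_record`s.
#' @export
read_cohort <- function(manifest_path) {
  dir <- dirname(manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  tps <- c("BL", "C2", "C4")
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    timepoints <- lapply(tps, function(tp) {
      vcol <- paste0("vol_", tp); mcol <- paste0("mask_", tp)
      if (is.null(row[[vcol]]) || is.na(row[[vcol]]))
        stop("manifest row for subject ", row$subject_id,
             " is missing column ", vcol)
      for (p in file.path(dir, c(row[[vcol]], row[[mcol]])))
        if (!file.exists(p))
          stop("subject ", row$subject_id, ": file not found: ", p)
      vol <- nifti_read(file.path(dir, row[[vcol]]))
      msk <- nifti_read(file.path(dir, row[[mcol]]))
      list(volume = vol, mask = roi_mask(msk$data, volume = vol),
           tumor_bed = NA)
    })
    names(timepoints) <- tps
    rec <- list(subject_id = row$subject_id, response = row$response,
                timepoints = timepoints,
                reader2_masks = NULL, reader1_repeat_masks = NULL)
    if (!is.null(row$reader2_mask_BL) && !is.na(row$reader2_mask_BL)) {
      rec$reader2_masks <- lapply(tps, function(tp) {
        v <- nifti_read(file.path(dir, row[[paste0("reader2_mask_", tp)]]))
        roi_mask(v$data, spacing = v$spacing)
      })
      names(rec$reader2_masks) <- tps
    }
    if (!is.null(row$repeat_mask_BL) && !is.na(row$repeat_mask_BL)) {
      rec$reader1_repeat_masks <- lapply(tps, function(tp) {
        v <- nifti_read(file.path(dir, row[[paste0("repeat_mask_", tp)]]))
        roi_mask(v$data, spacing = v$spacing)
      })
      names(rec$reader1_repeat_masks) <- tps
    }
    structure(rec, class = "subject_record")
  })
}
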
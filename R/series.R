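#' Dynamic 2D+t image series
#'
#' Container for a single-slice dynamic magnitude image stack, the unit of
#' analysis throughout the package (all in vivo analysis in the underlying
#' study was performed on the mid short-axis slice).
#'
#' @param frames Numeric array `nrow x ncol x n_frames` of magnitude
#'   intensities (arbitrary units, all >= 0).
#' @param pixel_spacing_mm Length-2 numeric, mm per pixel along (row, col).
#'   A scalar is recycled.
#' @param frame_times_s Strictly increasing frame mid-times in seconds, one
#'   per frame.
#' @param fov_mm Field of view in mm (row direction). Defaults to
#'   `nrow(frames) * pixel_spacing_mm[1]`.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(frames, pixel_spacing_mm, frame_times_s,
                           fov_mm = NULL) {
  frames <- unclass(frames)
  if (length(dim(frames)) != 3L) {
    abort("frames must be a 3-D array (row, col, frame)")
  }
  if (dim(frames)[3] != length(frame_times_s)) {
    abort("frame count must equal length(frame_times_s)")
  }
  if (!is_strictly_increasing(frame_times_s)) {
    abort("frame_times_s must be strictly increasing")
  }
  if (min(frames) < -1e-8 * max(abs(frames))) {
    abort("magnitude intensities must be nonnegative")
  }
  frames[frames < 0] <- 0
  pixel_spacing_mm <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  if (any(pixel_spacing_mm <= 0)) abort("pixel spacing must be positive")
  if (is.null(fov_mm)) fov_mm <- dim(frames)[1] * pixel_spacing_mm[1]
  structure(
    list(
      frames = frames,
      pixel_spacing_mm = pixel_spacing_mm,
      frame_times_s = as.numeric(frame_times_s),
      fov_mm = fov_mm
    ),
    class = "dynamic_series"
  )
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<dynamic_series> %d x %d pixels, %d frames, %.2f x %.2f mm, t = %.1f..%.1f s\n",
    d[1], d[2], d[3], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
    min(x$frame_times_s), max(x$frame_times_s)
  ))
  invisible(x)
}

#' @export
dim.dynamic_series <- function(x) dim(x$frames)

#' Number of dynamic frames
#' @param series A [dynamic_series()].
#' @return Integer frame count.
#' @export
n_frames <- function(series) dim(series$frames)[3]

# pixel-centre coordinates in mm, origin at the grid centre.
# Returns list(x = col coords, y = row coords) so that outer products give
# full coordinate grids; row i, col j centre is (x[j], y[i]).
pixel_centers <- function(n_row, n_col, spacing_mm) {
  list(
    x = (seq_len(n_col) - 0.5 - n_col / 2) * spacing_mm[2],
    y = (seq_len(n_row) - 0.5 - n_row / 2) * spacing_mm[1]
  )
}

#' Write a dynamic series to NIfTI or RDS
#'
#' `.nii`/`.nii.gz` stores the stack as an x-y-1-t volume with the pixel
#' spacing and the (uniform) frame interval in `pixdim`; non-uniform frame
#' times cannot be represented in NIfTI and raise an error. `.rds` stores
#' the full object and round-trips bit-exactly.
#'
#' @param series A [dynamic_series()].
#' @param path Output path ending in `.nii`, `.nii.gz` or `.rds`.
#' @return `path`, invisibly.
#' @export
write_dynamic_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(series, path)
    return(invisible(path))
  }
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    abort("path must end in .nii, .nii.gz or .rds")
  }
  dt <- grid_dt(series$frame_times_s)
  d <- dim(series$frames)
  vol <- array(series$frames, dim = c(d[1], d[2], 1L, d[3]))
  img <- RNifti::asNifti(vol)
  img <- RNifti::`pixdim<-`(img, c(series$pixel_spacing_mm, 10, dt))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a dynamic series from NIfTI, RDS or a raw array
#'
#' Accepts a 3-D NIfTI volume (axes x, y, t), a 4-D volume with a singleton
#' third (slice) axis, or an `.rds` file written by
#' [write_dynamic_series()]. A genuinely 3-D spatial volume (more than one
#' slice) is rejected: the package analyses one short-axis slice at a time.
#'
#' @param path Input path (`.nii`, `.nii.gz`, `.rds`).
#' @param frame_times_s Optional frame times overriding the NIfTI time step.
#' @return A [dynamic_series()].
#' @export
read_dynamic_series <- function(path, frame_times_s = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    out <- readRDS(path)
    if (!inherits(out, "dynamic_series")) {
      abort("RDS file does not contain a dynamic_series")
    }
    return(out)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  if (length(d) == 4L) {
    if (d[3] != 1L) {
      abort(paste0(
        "expected a single-slice 2D+t series but axis z has length ", d[3]
      ))
    }
    arr <- array(img[, , 1L, ], dim = c(d[1], d[2], d[4]))
    dt <- if (length(pd) >= 4) pd[4] else NA_real_
  } else if (length(d) == 3L) {
    arr <- img[, , , drop = FALSE]
    dt <- if (length(pd) >= 3) pd[3] else NA_real_
  } else {
    abort("NIfTI volume must be 3-D (x, y, t) or 4-D (x, y, 1, t)")
  }
  nt <- dim(arr)[3]
  if (is.null(frame_times_s)) {
    if (!is.finite(dt) || dt <= 0) {
      abort("frame interval missing from NIfTI header; supply frame_times_s")
    }
    frame_times_s <- (seq_len(nt) - 1) * dt
  }
  dynamic_series(arr, pixel_spacing_mm = pd[1:2],
                 frame_times_s = frame_times_s)
}

#' Myocardial / blood-pool region-of-interest set
#'
#' Holds epicardial and endocardial contours (polygons in mm, image-centred
#' coordinates), a left-ventricular blood-pool pixel mask, the reference
#' angle from which the six equiangular myocardial segments are counted, and
#' the segment count. Contours may be a single polygon (applied to every
#' frame, i.e. motion-corrected data) or a list with one polygon per frame.
#'
#' @param endo,epi Either an `n x 2` matrix of (x, y) vertices in mm, or a
#'   list of such matrices, one per frame. `NULL` entries mark frames with
#'   missing contours.
#' @param blood_pool Logical pixel matrix marking the LV blood-pool ROI.
#' @param ref_angle_deg Angle (degrees, anticlockwise from +x) at which
#'   segment 1 starts. Default 90 (anterior).
#' @param n_segments Number of equiangular segments. Default 6.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(endo, epi, blood_pool = NULL, ref_angle_deg = 90,
                    n_segments = 6L) {
  chk <- function(p, what) {
    if (is.null(p)) return(invisible())
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L) {
      abort(paste0(what, " contour must be an n x 2 matrix with n >= 3"))
    }
  }
  if (is.list(endo)) lapply(endo, chk, "endo") else chk(endo, "endo")
  if (is.list(epi)) lapply(epi, chk, "epi") else chk(epi, "epi")
  if (!is.null(blood_pool) && !is.logical(blood_pool)) {
    abort("blood_pool must be a logical matrix")
  }
  structure(
    list(
      endo = endo, epi = epi, blood_pool = blood_pool,
      ref_angle_deg = ref_angle_deg, n_segments = as.integer(n_segments)
    ),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  per_frame <- is.list(x$endo)
  cat(sprintf(
    "<roi_set> %s contours, %d segments from %g deg, blood pool: %s\n",
    if (per_frame) paste0(length(x$endo), " per-frame") else "static",
    x$n_segments, x$ref_angle_deg,
    if (is.null(x$blood_pool)) "none" else paste0(sum(x$blood_pool), " px")
  ))
  invisible(x)
}

# contour for a given frame; NULL if missing
roi_contour <- function(rois, which = c("endo", "epi"), frame) {
  which <- match.arg(which)
  p <- rois[[which]]
  if (is.list(p)) {
    if (frame > length(p)) return(NULL)
    p[[frame]]
  } else {
    p
  }
}

# polygon centroid (vertex mean is adequate for near-convex LV contours)
polygon_center <- function(p) colMeans(p)

# logical pixel mask of points inside polygon (mm coords, pixel centres)
polygon_mask <- function(p, n_row, n_col, spacing_mm) {
  pc <- pixel_centers(n_row, n_col, spacing_mm)
  gx <- matrix(pc$x, n_row, n_col, byrow = TRUE)
  gy <- matrix(pc$y, n_row, n_col)
  m <- pracma::inpolygon(as.vector(gx), as.vector(gy), p[, 1], p[, 2])
  matrix(m, n_row, n_col)
}

# run-length encode a logical matrix (column-major) for JSON export
rle_encode_mask <- function(m) {
  r <- rle(as.vector(m))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(dim = dim(m), runs = cbind(starts[keep], r$lengths[keep]))
}

rle_decode_mask <- function(enc) {
  m <- logical(prod(enc$dim))
  runs <- enc$runs
  if (length(runs)) {
    runs <- matrix(as.integer(runs), ncol = 2L)
    for (i in seq_len(nrow(runs))) {
      m[runs[i, 1] + seq_len(runs[i, 2]) - 1L] <- TRUE
    }
  }
  matrix(m, enc$dim[1], enc$dim[2])
}

#' Write an ROI set to JSON
#'
#' Static contours are stored once under `contours`; per-frame contours as
#' a `frames` map. The blood-pool mask is run-length encoded.
#'
#' @param rois A [roi_set()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  poly_l <- function(p) if (is.null(p)) NULL else unname(apply(p, 1, c, simplify = FALSE))
  obj <- list(
    ref_angle_deg = rois$ref_angle_deg,
    n_segments = rois$n_segments
  )
  if (is.list(rois$endo)) {
    obj$frames <- purrr::map2(
      rois$endo, rois$epi,
      function(en, ep) list(endo = poly_l(en), epi = poly_l(ep))
    )
  } else {
    obj$contours <- list(endo = poly_l(rois$endo), epi = poly_l(rois$epi))
  }
  if (!is.null(rois$blood_pool)) {
    enc <- rle_encode_mask(rois$blood_pool)
    obj$blood_pool <- list(dim = enc$dim,
                           runs = unname(apply(enc$runs, 1, c, simplify = FALSE)))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI set from JSON
#'
#' @param path JSON path written by [write_roi_set()].
#' @return A [roi_set()].
#' @export
read_roi_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_poly <- function(p) {
    if (is.null(p) || length(p) == 0) return(NULL)
    do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
  }
  bp <- NULL
  if (!is.null(obj$blood_pool)) {
    runs <- do.call(rbind, lapply(obj$blood_pool$runs,
                                  function(v) as.integer(unlist(v))))
    bp <- rle_decode_mask(list(dim = as.integer(unlist(obj$blood_pool$dim)),
                               runs = runs))
  }
  if (!is.null(obj$frames)) {
    endo <- lapply(obj$frames, function(f) as_poly(f$endo))
    epi <- lapply(obj$frames, function(f) as_poly(f$epi))
  } else {
    endo <- as_poly(obj$contours$endo)
    epi <- as_poly(obj$contours$epi)
  }
  roi_set(endo, epi, blood_pool = bp,
          ref_angle_deg = as.numeric(obj$ref_angle_deg),
          n_segments = as.integer(obj$n_segments %||% 6L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
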
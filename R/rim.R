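# --- wall-depth geometry -----------------------------------------------
# Per-pixel fractional wall depth (0 at endocardium, 1 at epicardium) for
# pixels inside the myocardium, NA elsewhere. Contour radii are linearly
# interpolated in angle around the LV centre.
wall_depth_map <- function(endo, epi, n_row, n_col, spacing_mm) {
  ctr <- polygon_center(endo)
  pc <- pixel_centers(n_row, n_col, spacing_mm)
  gx <- matrix(pc$x, n_row, n_col, byrow = TRUE) - ctr[1]
  gy <- matrix(pc$y, n_row, n_col) - ctr[2]
  r <- sqrt(gx^2 + gy^2)
  th <- atan2(gy, gx) %% (2 * pi)
  r_endo <- contour_radius_at(endo, ctr, th)
  r_epi <- contour_radius_at(epi, ctr, th)
  depth <- (r - r_endo) / (r_epi - r_endo)
  myo <- polygon_mask(epi, n_row, n_col, spacing_mm) &
    !polygon_mask(endo, n_row, n_col, spacing_mm)
  depth[!myo] <- NA_real_
  depth
}

# radius of a polygon (about centre ctr) at each query angle, by linear
# interpolation of vertex radius against vertex angle
contour_radius_at <- function(p, ctr, theta) {
  vx <- p[, 1] - ctr[1]; vy <- p[, 2] - ctr[2]
  va <- atan2(vy, vx) %% (2 * pi)
  vr <- sqrt(vx^2 + vy^2)
  o <- order(va)
  va <- va[o]; vr <- vr[o]
  # wrap for periodic interpolation
  va2 <- c(va[length(va)] - 2 * pi, va, va[1] + 2 * pi)
  vr2 <- c(vr[length(vr)], vr, vr[1])
  m <- stats::approx(va2, vr2, xout = as.vector(theta))$y
  matrix(m, nrow(theta), ncol(theta))
}

# drop 4-connected components smaller than min_px (EBImage labelling)
filter_small_components <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Detect subendocardial dark-rim artifact pixels
#'
#' Automates the visual identification of the hypointense subendocardial
#' band: on each searched frame, rim pixels are myocardial pixels in the
#' inner half of the wall whose signal falls more than `threshold_sd`
#' standard deviations below the mean of the remote (outer-half) myocardium
#' of the same frame; 4-connected components smaller than `min_component`
#' pixels are discarded as noise.
#'
#' The SD scale is estimated from the remote myocardium on the pre-contrast
#' baseline frames (pooled across pixels and frames after removing each
#' frame's remote mean) — the frames a reader uses to judge what "normal"
#' myocardial texture looks like before the bolus arrives. During contrast
#' transit the remote myocardium itself carries edge ringing, so a
#' same-frame SD would desensitize detection exactly when the artifact is
#' largest. If no baseline frames can be identified the same-frame remote
#' SD is used as a fallback.
#'
#' @param series A [dynamic_series()].
#' @param rois A [roi_set()].
#' @param search_frames Frames to search. Default: the first-pass window of
#'   the blood-pool curve (rim artifacts occur during contrast transit); if
#'   no blood-pool mask is available, all frames.
#' @param baseline_frames Pre-contrast frames for the SD estimate; default
#'   detected from the blood-pool curve.
#' @param inner_frac Wall-depth fraction defining the subendocardial band.
#'   Default 0.5.
#' @param threshold_sd Threshold in remote-myocardium SDs. Default 2.
#' @param min_component Minimum component size in pixels. Default 3.
#' @return A list of logical rim masks, one per frame (`NULL` outside
#'   `search_frames`), with attribute `"search_frames"`.
#' @export
detect_rim <- function(series, rois, search_frames = NULL,
                       baseline_frames = NULL,
                       inner_frac = 0.5, threshold_sd = 2,
                       min_component = 3L) {
  stopifnot(inherits(series, "dynamic_series"), inherits(rois, "roi_set"))
  d <- dim(series$frames)
  nt <- d[3]
  if ((is.null(search_frames) || is.null(baseline_frames)) &&
      !is.null(rois$blood_pool)) {
    bp_si <- vapply(seq_len(nt),
                    function(f) mean(series$frames[, , f][rois$blood_pool]),
                    numeric(1))
    aif_raw <- si_curve(series$frame_times_s, bp_si)
    bl <- detect_baseline_frames(aif_raw)
    if (is.null(baseline_frames)) baseline_frames <- bl
    if (is.null(search_frames)) {
      search_frames <- seq_len(nt)
      if (length(bl) >= 2L) {
        aif <- baseline_equalize(set_baseline_frames(aif_raw, bl))
        w <- try(first_pass_window(aif), silent = TRUE)
        if (!inherits(w, "try-error")) search_frames <- w$start:w$end
      }
    }
  }
  if (is.null(search_frames)) search_frames <- seq_len(nt)
  static <- !is.list(rois$endo)
  depth <- NULL
  noise_sd <- NULL
  masks <- vector("list", nt)
  for (f in intersect(search_frames, seq_len(nt))) {
    if (is.null(depth) || !static) {
      endo <- roi_contour(rois, "endo", f)
      epi <- roi_contour(rois, "epi", f)
      if (is.null(endo) || is.null(epi)) {
        abort(paste0("missing contour on frame ", f))
      }
      depth <- wall_depth_map(endo, epi, d[1], d[2],
                              series$pixel_spacing_mm)
      if (!any(!is.na(depth))) abort("no myocardial pixels inside contours")
      noise_sd <- NULL
    }
    inner <- !is.na(depth) & depth < inner_frac
    remote <- !is.na(depth) & depth >= inner_frac
    if (is.null(noise_sd)) {
      if (length(baseline_frames) >= 1L && static) {
        resid <- unlist(lapply(baseline_frames, function(b) {
          v <- series$frames[, , b][remote]
          v - mean(v)
        }))
        noise_sd <- sqrt(mean(resid^2))
      } else {
        noise_sd <- NA_real_ # fall back to same-frame SD below
      }
    }
    img <- series$frames[, , f]
    s <- if (is.na(noise_sd)) sd(img[remote]) else noise_sd
    thr <- mean(img[remote]) - threshold_sd * s
    rim <- inner & img < thr
    masks[[f]] <- filter_small_components(rim, min_component)
  }
  attr(masks, "search_frames") <- search_frames
  masks
}

#' Dark-rim artifact thickness
#'
#' Maximum radial extent of the rim mask along rays cast from the LV
#' centre, in mm — the automated analogue of an electronic-caliper
#' measurement on the most prominent frame. Rays are sampled densely
#' (`n_rays` directions, radial step `spacing/8`); each contiguous in-mask
#' run along a ray is reduced to the number of one-pixel radial shells it
#' spans, counted from its innermost pixel (`floor` of the centre-radius
#' span plus one, so a diagonal crossing of a one-pixel ring still reads
#' one pixel), and the maximum over rays, times the pixel spacing, is
#' returned.
#'
#' @param mask Logical rim mask (one frame).
#' @param rois A [roi_set()] (provides the LV centre via the endocardial
#'   contour of `frame`).
#' @param spacing_mm Pixel spacing, mm (scalar or length-2).
#' @param frame Frame whose contour to use when contours are per-frame.
#' @param n_rays Number of ray directions. Default 720.
#' @return Thickness in mm; 0 with attribute `flag = "empty"` for an empty
#'   mask.
#' @export
rim_thickness <- function(mask, rois, spacing_mm, frame = 1L,
                          n_rays = 720L) {
  if (!any(mask)) {
    out <- 0
    attr(out, "flag") <- "empty"
    return(out)
  }
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
  ctr <- polygon_center(roi_contour(rois, "endo", frame))
  n_row <- nrow(mask); n_col <- ncol(mask)
  # work in row-pixel units so that mm = pixels x spacing holds exactly
  step_px <- 1 / 8
  aniso <- spacing_mm[1] / spacing_mm[2]
  ctr_px <- c(ctr[1] / spacing_mm[2], ctr[2] / spacing_mm[1])
  # pixel-centre radii about the LV centre, in row-pixel units
  gx <- (matrix(seq_len(n_col), n_row, n_col, byrow = TRUE) - 0.5 -
           n_col / 2 - ctr_px[1]) / aniso
  gy <- matrix(seq_len(n_row), n_row, n_col) - 0.5 - n_row / 2 - ctr_px[2]
  r_center <- sqrt(gx^2 + gy^2)
  r_max_px <- sqrt(sum(c(n_row, n_col)^2)) / 2
  radii_px <- seq(0, r_max_px, by = step_px)
  th <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  best_px <- 0
  for (a in th) {
    col <- floor(ctr_px[1] + radii_px * cos(a) * aniso + n_col / 2) + 1L
    row <- floor(ctr_px[2] + radii_px * sin(a) + n_row / 2) + 1L
    ok <- row >= 1L & row <= n_row & col >= 1L & col <= n_col
    hit <- rep(FALSE, length(radii_px))
    hit[ok] <- mask[cbind(row[ok], col[ok])]
    if (any(hit)) {
      # radial shell span of each contiguous in-mask run, counted from
      # the run's innermost pixel
      runs <- rle(hit)
      ends <- cumsum(runs$lengths)
      for (q in which(runs$values)) {
        idx <- (ends[q] - runs$lengths[q] + 1L):ends[q]
        rs <- r_center[cbind(row[idx], col[idx])]
        best_px <- max(best_px, floor(diff(range(rs)) + 1e-9) + 1)
      }
    }
  }
  best_px * spacing_mm[1]
}

#' Dark-rim artifact extent
#'
#' Rim area as a percentage of the myocardial slice area on one frame.
#'
#' @param mask Logical rim mask.
#' @param rois A [roi_set()].
#' @param spacing_mm Pixel spacing, mm.
#' @param frame Frame index for per-frame contours.
#' @return Extent in percent (0-100).
#' @export
rim_extent <- function(mask, rois, spacing_mm, frame = 1L) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
  endo <- roi_contour(rois, "endo", frame)
  epi <- roi_contour(rois, "epi", frame)
  myo <- polygon_mask(epi, nrow(mask), ncol(mask), spacing_mm) &
    !polygon_mask(endo, nrow(mask), ncol(mask), spacing_mm)
  if (!any(myo)) abort("empty myocardium: cannot compute extent")
  100 * sum(mask & myo) / sum(myo)
}

#' Dark-rim artifact duration
#'
#' @param masks List of per-frame rim masks (from [detect_rim()]).
#' @return Number of frames with a nonempty rim mask.
#' @export
rim_duration <- function(masks) {
  sum(vapply(masks, function(m) !is.null(m) && any(m), logical(1)))
}

#' Measure the dark-rim artifact of a study
#'
#' Detects rim pixels over the searched frames, picks the most prominent
#' frame (largest rim area), and reports thickness there, extent there,
#' duration, and the prominent frame index.
#'
#' @inheritParams detect_rim
#' @param ... Passed to [detect_rim()].
#' @return A one-row tibble: `thickness_mm`, `extent_pct`,
#'   `duration_frames`, `prominent_frame`.
#' @export
measure_rim <- function(series, rois, ...) {
  masks <- detect_rim(series, rois, ...)
  areas <- vapply(masks, function(m) if (is.null(m)) 0L else sum(m),
                  integer(1))
  if (all(areas == 0L)) {
    return(tibble(thickness_mm = 0, extent_pct = 0, duration_frames = 0L,
                  prominent_frame = NA_integer_))
  }
  pf <- which.max(areas)
  sp <- series$pixel_spacing_mm
  tibble(
    thickness_mm = as.numeric(rim_thickness(masks[[pf]], rois, sp,
                                            frame = pf)),
    extent_pct = rim_extent(masks[[pf]], rois, sp, frame = pf),
    duration_frames = rim_duration(masks),
    prominent_frame = as.integer(pf)
  )
}

#' Rim artifact versus acquired matrix experiment
#'
#' Renders one noiseless phantom and acquires it at several acquired-matrix
#' sizes under a fixed field of view and reconstruction matrix, measuring
#' the dark rim each time — the spatial-resolution half of the
#' spatial-versus-temporal comparison. Higher acquired matrices truncate
#' less k-space and ring less.
#'
#' @param acq_matrices Acquired matrix sizes. Default `c(128, 192, 256)`.
#' @param cfg A [phantom_config()]; noise and motion default to zero here.
#' @return A tibble with one row per matrix: measurements plus `voxel_mm`.
#' @export
rim_matrix_experiment <- function(acq_matrices = c(128L, 192L, 256L),
                                  cfg = NULL) {
  if (is.null(cfg)) {
    cfg <- phantom_config(noise_sigma = 0, motion_amp_mm = 0)
  }
  rend <- render_series(cfg)
  out <- purrr::map(acq_matrices, function(m) {
    sp <- tibble(name = paste0("matrix_", m), acq_matrix = as.integer(m),
                 recon_matrix = cfg$grid)
    acq <- acquire_series(rend$series, sp, cfg)
    mutate(measure_rim(acq, rend$rois), acq_matrix = as.integer(m),
           voxel_mm = voxel_size(cfg$fov_mm, m))
  })
  bind_rows(out)
}
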
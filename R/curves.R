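#' Signal-intensity-time curve
#'
#' The elementary measurement of first-pass perfusion analysis: one signal
#' sample per dynamic frame for a region (a myocardial segment or the LV
#' blood pool), with the pre-contrast baseline frames flagged.
#'
#' @param t_s Strictly increasing sample times in seconds.
#' @param si Signal intensity in arbitrary units, same length as `t_s`.
#' @param baseline_frames Integer indices of pre-contrast frames; they must
#'   precede every non-baseline frame.
#' @return A tibble with columns `t_s`, `si`, `is_baseline`.
#' @export
si_curve <- function(t_s, si, baseline_frames = integer()) {
  if (length(t_s) != length(si)) abort("t_s and si lengths differ")
  if (!is_strictly_increasing(t_s)) abort("t_s must be strictly increasing")
  baseline_frames <- as.integer(baseline_frames)
  if (length(baseline_frames) &&
      !identical(sort(baseline_frames), seq_along(baseline_frames))) {
    abort("baseline frames must be a leading block 1..k")
  }
  tibble(
    t_s = as.numeric(t_s),
    si = as.numeric(si),
    is_baseline = seq_along(t_s) %in% baseline_frames
  )
}

assert_si_curve <- function(c, what = "curve") {
  need <- c("t_s", "si", "is_baseline")
  if (!is.data.frame(c) || !all(need %in% names(c))) {
    abort(paste0(what, " must be an si_curve tibble (t_s, si, is_baseline)"))
  }
}

#' Extract segment and blood-pool signal curves from a dynamic series
#'
#' Assigns each pixel whose centre lies inside the epicardial contour but
#' outside the endocardial contour to the myocardium, splits the myocardium
#' into `n_segments` equiangular sextants counted anticlockwise from the
#' reference angle, and averages signal per region per frame. The LV
#' blood-pool curve is the mean over the blood-pool mask. Pixels in an
#' optional rim mask (suspected dark-rim artifact) are excluded from the
#' myocardium, mirroring the practice of contouring around suspected
#' artifact.
#'
#' @param series A [dynamic_series()].
#' @param rois A [roi_set()] with contours for every frame and a blood-pool
#'   mask.
#' @param rim_masks Optional list of logical rim masks (one per frame) to
#'   exclude, e.g. from [detect_rim()].
#' @param seg_masks Optional precomputed segment masks (list of logical
#'   matrices) for static contours, e.g. to amortize geometry over many
#'   noise realizations of one phantom.
#' @return A tibble in long format: `region` (`"segment_1"` ...
#'   `"segment_6"`, `"blood_pool"`), `frame`, `t_s`, `si`.
#' @export
extract_si_curves <- function(series, rois, rim_masks = NULL,
                              seg_masks = NULL) {
  stopifnot(inherits(series, "dynamic_series"), inherits(rois, "roi_set"))
  d <- dim(series$frames)
  nt <- d[3]
  if (is.null(rois$blood_pool)) abort("rois must include a blood-pool mask")
  static <- !is.list(rois$endo)
  if (!is.null(seg_masks) && !static) {
    abort("precomputed seg_masks require static contours")
  }
  rows <- vector("list", nt)
  for (f in seq_len(nt)) {
    if (is.null(seg_masks) || !static) {
      endo <- roi_contour(rois, "endo", f)
      epi <- roi_contour(rois, "epi", f)
      if (is.null(endo) || is.null(epi)) {
        abort(paste0("missing myocardial contour on frame ", f))
      }
      seg_masks <- segment_masks(endo, epi, d[1], d[2],
                                 series$pixel_spacing_mm,
                                 rois$ref_angle_deg, rois$n_segments)
    }
    masks <- seg_masks
    if (!is.null(rim_masks) && !is.null(rim_masks[[f]])) {
      masks <- lapply(masks, function(m) m & !rim_masks[[f]])
    }
    img <- series$frames[, , f]
    si <- vapply(seq_along(masks), function(s) {
      m <- masks[[s]]
      if (!any(m)) {
        abort(paste0("empty myocardial segment ", s, " on frame ", f))
      }
      mean(img[m])
    }, numeric(1))
    rows[[f]] <- tibble(
      region = c(paste0("segment_", seq_along(masks)), "blood_pool"),
      frame = f,
      t_s = series$frame_times_s[f],
      si = c(si, mean(img[rois$blood_pool]))
    )
  }
  bind_rows(rows)
}

# equiangular segment masks of the myocardial annulus between two contours
segment_masks <- function(endo, epi, n_row, n_col, spacing_mm,
                          ref_angle_deg, n_segments) {
  myo <- polygon_mask(epi, n_row, n_col, spacing_mm) &
    !polygon_mask(endo, n_row, n_col, spacing_mm)
  ctr <- polygon_center(endo)
  pc <- pixel_centers(n_row, n_col, spacing_mm)
  gx <- matrix(pc$x, n_row, n_col, byrow = TRUE) - ctr[1]
  gy <- matrix(pc$y, n_row, n_col) - ctr[2]
  theta <- (atan2(gy, gx) - ref_angle_deg * pi / 180) %% (2 * pi)
  seg <- pmin(floor(theta / (2 * pi / n_segments)) + 1L, n_segments)
  lapply(seq_len(n_segments), function(s) myo & seg == s)
}

#' Pull one region's curve as an si_curve tibble
#'
#' @param curves Long tibble from [extract_si_curves()].
#' @param region Region label, e.g. `"blood_pool"` or `"segment_3"`.
#' @param baseline_frames Baseline frame indices; default none.
#' @return An [si_curve()] tibble.
#' @export
curve_pluck <- function(curves, region, baseline_frames = integer()) {
  cc <- curves[curves$region == region, ]
  if (!nrow(cc)) abort(paste0("no region '", region, "' in curves"))
  si_curve(cc$t_s, cc$si, baseline_frames)
}

#' Detect pre-contrast baseline frames from an arterial input curve
#'
#' Baseline frames are all frames before the curve first exceeds 5% of its
#' peak enhancement (peak minus minimum). The in vivo analogue is the
#' operator marking the pre-contrast frames by eye.
#'
#' @param aif Blood-pool [si_curve()] (raw intensities).
#' @param frac Enhancement fraction defining bolus arrival. Default 0.05.
#' @return Integer vector of baseline frame indices (possibly empty).
#' @export
detect_baseline_frames <- function(aif, frac = 0.05) {
  assert_si_curve(aif, "aif")
  lo <- min(aif$si)
  rng <- max(aif$si) - lo
  if (rng <= 0) return(integer())
  cross <- which(aif$si - lo > frac * rng)[1]
  if (is.na(cross) || cross == 1L) return(integer())
  seq_len(cross - 1L)
}

#' Mark baseline frames on a curve
#'
#' @param c An [si_curve()] tibble.
#' @param baseline_frames Leading frame indices to flag as baseline.
#' @return The curve with `is_baseline` updated.
#' @export
set_baseline_frames <- function(c, baseline_frames) {
  assert_si_curve(c)
  si_curve(c$t_s, c$si, baseline_frames)
}

#' Equalize a curve's pre-contrast baseline to zero
#'
#' Subtracts the mean signal over the flagged baseline frames, the
#' curve-conditioning step applied before deconvolution so that blood-pool
#' and myocardial curves share a common zero.
#'
#' @param c An [si_curve()] with at least two baseline frames.
#' @return The curve shifted so its baseline-frame mean is exactly zero.
#' @export
baseline_equalize <- function(c) {
  assert_si_curve(c)
  nb <- sum(c$is_baseline)
  if (nb < 2L) abort("need at least 2 baseline frames to equalize")
  mutate(c, si = .data$si - mean(.data$si[.data$is_baseline]))
}

#' Locate the first pass of contrast on an arterial input curve
#'
#' The first pass starts where the (baseline-equalized) curve first exceeds
#' 5% of its peak and ends at the first local minimum after the peak — the
#' trough before recirculation — or at the last frame if the curve never
#' turns back up. Either endpoint can be overridden manually.
#'
#' @param aif Baseline-equalized blood-pool [si_curve()] with a positive
#'   peak.
#' @param frac Fraction of peak defining the start. Default 0.05.
#' @param start,end Optional manual overrides (frame indices).
#' @return A list with integer elements `start` and `end`.
#' @export
first_pass_window <- function(aif, frac = 0.05, start = NULL, end = NULL) {
  assert_si_curve(aif, "aif")
  peak <- max(aif$si)
  if (!is.finite(peak) || peak <= 0) {
    abort("no positive enhancement peak: cannot locate first pass")
  }
  pk <- which.max(aif$si)
  if (is.null(start)) {
    start <- which(aif$si > frac * peak)[1]
    if (is.na(start)) abort("curve never exceeds the start threshold")
  }
  if (is.null(end)) {
    n <- length(aif$si)
    end <- n
    if (pk < n - 1L) {
      for (i in seq(pk + 1L, n - 1L)) {
        if (aif$si[i] < aif$si[i - 1L] && aif$si[i + 1L] > aif$si[i]) {
          end <- i
          break
        }
      }
    }
  }
  start <- as.integer(start); end <- as.integer(end)
  if (!(start <= pk && pk <= end)) {
    abort("first-pass window must bracket the peak")
  }
  list(start = start, end = end)
}

#' Write extracted curves to CSV
#'
#' @param curves Long tibble from [extract_si_curves()], optionally with an
#'   `is_baseline` column.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_si_curves <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}

#' Read curves written by [write_si_curves()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_si_curves <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
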
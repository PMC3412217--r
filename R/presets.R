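#' Sequence-profile presets for the four perfusion acquisitions
#'
#' Returns the pulse-sequence geometries compared in the underlying study:
#' a twofold SENSE-accelerated reference and three 8-fold k-t SENSE
#' variants that invest the speed-up in spatial resolution (`kt_high`),
#' acquisition-window duration (`kt_fast`) or both (`kt_hybrid`). All four
#' share a 256-line reconstruction matrix; the acquired matrix and per-slice
#' acquisition window differ. `voxel_mm` is the frequency-direction acquired
#' in-plane voxel size at the stated field of view.
#'
#' The k-t acquisitions ran for 24 or 32 dynamic frames (32 is the preset
#' default); the SENSE reference was stopped manually at the second pass of
#' contrast, so its frame count is `NA` (variable, at most 60).
#'
#' @param fov_mm Field of view in mm (study median 340 mm).
#' @return A tibble with one row per sequence: `name`, `acceleration`,
#'   `acq_matrix`, `recon_matrix`, `acq_window_ms`, `fov_mm`, `n_frames`,
#'   `voxel_mm`.
#' @examples
#' sequence_profiles()
#' @export
sequence_profiles <- function(fov_mm = 340) {
  tibble(
    name          = c("SENSE", "kt_high", "kt_fast", "kt_hybrid"),
    acceleration  = c(2, 8, 8, 8),
    acq_matrix    = c(128L, 256L, 128L, 192L),
    recon_matrix  = 256L,
    acq_window_ms = c(119, 117, 64, 109),
    fov_mm        = fov_mm,
    n_frames      = c(NA_integer_, 32L, 32L, 32L),
    voxel_mm      = voxel_size(fov_mm, c(128, 256, 128, 192))
  )
}

#' Fetch a single sequence profile by name
#'
#' @param name One of `"SENSE"`, `"kt_high"`, `"kt_fast"`, `"kt_hybrid"`.
#' @param fov_mm Field of view in mm.
#' @param n_frames Optional dynamic frame count override (the k-t sequences
#'   used 24 or 32 frames depending on breath-hold capability).
#' @return A one-row tibble (see [sequence_profiles()]).
#' @export
sequence_profile <- function(name, fov_mm = 340, n_frames = NULL) {
  sp <- sequence_profiles(fov_mm)
  sp <- sp[sp$name == name, ]
  if (nrow(sp) != 1L) {
    abort(paste0("unknown sequence profile '", name, "'"))
  }
  if (!is.null(n_frames)) sp$n_frames <- as.integer(n_frames)
  sp
}

#' Acquired in-plane voxel size
#'
#' Frequency-direction voxel dimension, `fov_mm / acq_matrix`, rounded half
#' away from zero to two decimals as conventionally quoted on scan cards
#' (e.g. 340 mm / 128 lines = 2.66 mm).
#'
#' @param fov_mm Field of view (mm), positive.
#' @param acq_matrix Number of acquired lines, at least 1. Vectorised.
#' @return Voxel size(s) in mm, rounded to 2 decimals.
#' @examples
#' voxel_size(340, c(128, 192, 256))
#' @export
voxel_size <- function(fov_mm, acq_matrix) {
  if (any(!is.finite(fov_mm)) || any(fov_mm <= 0)) {
    abort("fov_mm must be positive")
  }
  if (any(!is.finite(acq_matrix)) || any(acq_matrix < 1)) {
    abort("acq_matrix must be >= 1")
  }
  # scale before dividing so exact half-cases (e.g. 69/120 mm) stay
  # representable and round away from zero as intended
  round_half_away((100 * fov_mm) / acq_matrix) / 100
}

#' Per-pixel readout bandwidth from the water-fat shift
#'
#' On Philips systems readout bandwidth is specified through the water-fat
#' shift (WFS) in pixels: bandwidth = chemical-shift frequency / WFS, with
#' the fat-water chemical shift `shift_ppm` x gamma x B0. At 1.5 T with the
#' conventional 3.4 ppm shift, a WFS of 0.35 pixels corresponds to about
#' 620 Hz per pixel.
#'
#' @param wfs_pixels Water-fat shift in pixels, positive.
#' @param field_t Main field strength in tesla. Default 1.5.
#' @param shift_ppm Fat-water chemical shift in ppm. Default 3.4.
#' @param gamma_mhz_per_t Proton gyromagnetic ratio in MHz/T. Default 42.577.
#' @return Bandwidth in Hz per pixel.
#' @examples
#' pixel_bandwidth(0.35) # ~620 Hz
#' @export
pixel_bandwidth <- function(wfs_pixels, field_t = 1.5, shift_ppm = 3.4,
                            gamma_mhz_per_t = 42.577) {
  args <- c(wfs_pixels, field_t, shift_ppm, gamma_mhz_per_t)
  if (any(!is.finite(args)) || any(args <= 0)) {
    abort("all inputs must be positive")
  }
  (shift_ppm * 1e-6 * gamma_mhz_per_t * 1e6 * field_t) / wfs_pixels
}

#' Export sequence presets as YAML
#'
#' @param path Output file path.
#' @param fov_mm Field of view passed to [sequence_profiles()].
#' @return `path`, invisibly.
#' @export
write_sequence_profiles <- function(path, fov_mm = 340) {
  sp <- sequence_profiles(fov_mm)
  out <- purrr::transpose(as.list(sp))
  names(out) <- sp$name
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read sequence profiles back from YAML
#'
#' @param path YAML file written by [write_sequence_profiles()].
#' @return A tibble with the same columns as [sequence_profiles()].
#' @export
read_sequence_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- bind_rows(lapply(raw, as_tibble))
  out$acq_matrix <- as.integer(out$acq_matrix)
  out$recon_matrix <- as.integer(out$recon_matrix)
  out$n_frames <- as.integer(out$n_frames)
  out
}
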
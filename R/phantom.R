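#' Gamma-variate arterial input parameters
#'
#' Parameterizes the LV blood-pool enhancement of a compact contrast bolus
#' (0.05 mmol/kg at 5 ml/s in the emulated protocol):
#' `baseline + amplitude * (t - t0)^alpha * exp(-(t - t0) / beta)` after
#' arrival at `t0_s`. Defaults give a bolus arriving at 8 s that peaks near
#' 12 s at about 100 a.u. over a 10 a.u. pre-contrast baseline.
#'
#' @param amplitude Scale in a.u. (peak height depends on alpha, beta too).
#' @param t0_s Bolus arrival time, s.
#' @param alpha Shape (> 0), controls upslope steepness.
#' @param beta_s Time scale (> 0), s.
#' @param baseline Pre-contrast signal offset, a.u.
#' @return A list of class `aif_params`.
#' @export
aif_params <- function(amplitude = 45, t0_s = 8, alpha = 2.5, beta_s = 1.5,
                       baseline = 10) {
  if (alpha <= 0) abort("alpha must be positive")
  if (beta_s <= 0) abort("beta_s must be positive")
  if (amplitude < 0) abort("amplitude must be nonnegative")
  structure(
    list(amplitude = amplitude, t0_s = t0_s, alpha = alpha,
         beta_s = beta_s, baseline = baseline),
    class = "aif_params"
  )
}

#' Evaluate a gamma-variate arterial input function
#'
#' @param t_s Monotone increasing sample times, s.
#' @param p An [aif_params()].
#' @return An [si_curve()] whose baseline frames are those at or before
#'   `t0_s`.
#' @export
gamma_variate_aif <- function(t_s, p) {
  stopifnot(inherits(p, "aif_params"))
  if (!is_strictly_increasing(t_s)) abort("t_s must be monotone increasing")
  u <- t_s - p$t0_s
  si <- ifelse(u <= 0, 0, p$amplitude * u^p$alpha * exp(-u / p$beta_s))
  si_curve(t_s, p$baseline + si, baseline_frames = which(t_s <= p$t0_s))
}

# closed-form area above baseline of the gamma-variate bolus
gamma_variate_area <- function(p) {
  p$amplitude * gamma(p$alpha + 1) * p$beta_s^(p$alpha + 1)
}

#' Fermi impulse-response model
#'
#' The constrained impulse response used for deconvolution:
#' `R(t) = A / (1 + exp((t - T0) / W))` for `t >= delay`, zero before. The
#' initial height `R(delay+)` equals tissue flow per unit volume, so
#' MBF (ml/min/g, unit tissue density) is `60 * A / (1 + exp(-T0 / W))`.
#'
#' @param A_per_s Amplitude, 1/s (>= 0).
#' @param T0_s Shoulder duration before decay, s (>= 0).
#' @param W_s Decay width, s (> 0).
#' @param delay_s Bolus-arrival delay between LV and myocardium, s (>= 0).
#' @return A list of class `fermi_model`.
#' @export
fermi_model <- function(A_per_s, T0_s = 4, W_s = 3, delay_s = 0) {
  if (W_s <= 0) abort("W_s must be positive")
  if (A_per_s < 0) abort("A_per_s must be nonnegative")
  if (T0_s < 0 || delay_s < 0) abort("T0_s and delay_s must be nonnegative")
  structure(
    list(A_per_s = A_per_s, T0_s = T0_s, W_s = W_s, delay_s = delay_s),
    class = "fermi_model"
  )
}

#' Fermi model with amplitude set from a target blood flow
#'
#' @param mbf_ml_min_g Myocardial blood flow, ml/min/g.
#' @inheritParams fermi_model
#' @return A [fermi_model()] whose initial height equals `mbf / 60`.
#' @export
fermi_model_from_mbf <- function(mbf_ml_min_g, T0_s = 4, W_s = 3,
                                 delay_s = 0) {
  A <- (mbf_ml_min_g / 60) * (1 + exp(-T0_s / W_s))
  fermi_model(A, T0_s, W_s, delay_s)
}

#' Blood flow implied by a Fermi model
#'
#' @param f A [fermi_model()].
#' @return MBF in ml/min/g: `60 * R(delay+)`.
#' @export
fermi_mbf <- function(f) {
  stopifnot(inherits(f, "fermi_model"))
  60 * f$A_per_s / (1 + exp(-f$T0_s / f$W_s))
}

#' Evaluate a Fermi impulse response on a time grid
#'
#' @param t_s Monotone time grid starting at 0, s.
#' @param f A [fermi_model()].
#' @return Numeric vector, 1/s; zero before the delay, monotone
#'   nonincreasing after.
#' @export
fermi_irf <- function(t_s, f) {
  stopifnot(inherits(f, "fermi_model"))
  if (!is_strictly_increasing(t_s)) abort("t_s must be monotone increasing")
  if (t_s[1] < 0) abort("t_s must start at or after 0")
  u <- t_s - f$delay_s
  # guard exp overflow for t far beyond T0 at small W
  z <- pmin((u - f$T0_s) / f$W_s, 700)
  ifelse(u < 0, 0, f$A_per_s / (1 + exp(z)))
}

#' Forward model: myocardial curve from AIF and impulse response
#'
#' Discrete causal convolution (rectangle rule) of the baseline-subtracted
#' AIF with the impulse response, plus a tissue pre-contrast baseline —
#' the forward model whose inversion is Fermi-constrained deconvolution.
#'
#' @param aif An [si_curve()] on a uniform grid.
#' @param irf Impulse response sampled on the same grid (from t = 0), 1/s.
#' @param dt Frame interval, s. Defaults to the AIF grid spacing.
#' @param baseline Tissue pre-contrast signal, a.u. Default 0.
#' @return An [si_curve()] on the AIF grid.
#' @export
tissue_curve <- function(aif, irf, dt = NULL, baseline = 0) {
  assert_si_curve(aif, "aif")
  if (length(irf) != nrow(aif)) {
    abort("aif and irf must be sampled on the same grid")
  }
  if (is.null(dt)) dt <- grid_dt(aif$t_s)
  a <- aif$si - if (any(aif$is_baseline)) mean(aif$si[aif$is_baseline]) else 0
  y <- causal_convolve(a, irf) * dt
  si_curve(aif$t_s, baseline + y, baseline_frames = which(aif$is_baseline))
}

# discrete causal convolution: y[k] = sum_{j<=k} a[j] h[k-j+1]
causal_convolve <- function(a, h) {
  n <- length(a)
  convolve(a, rev(h), type = "open")[seq_len(n)]
}

#' Phantom configuration
#'
#' Geometry and acquisition-physics settings for the concentric-disc
#' short-axis phantom: a bright LV blood disc out to the endocardial radius,
#' a myocardial annulus between the endo- and epicardial radii, zero
#' background. The blood-pool ROI is the conservative `r_cavity_mm` disc
#' (drawn well inside the cavity, as one avoids papillary muscles and edge
#' pixels in vivo). Defaults: 340 mm field of view on a 256 grid, 25/35 mm
#' endo/epi radii (10 mm wall), stress-level flow 3.5 ml/min/g, and noise
#' sigma set for a peak-LV image SNR of 40.
#'
#' @param grid Reconstruction matrix (pixels per side).
#' @param fov_mm Field of view, mm.
#' @param r_cavity_mm Blood-pool ROI radius, mm (< `r_endo_mm`).
#' @param r_endo_mm Endocardial radius, mm.
#' @param r_epi_mm Epicardial radius, mm.
#' @param mbf_ml_min_g True myocardial blood flow, ml/min/g.
#' @param aif An [aif_params()].
#' @param t0_s,w_s Fermi shoulder and width of the generating impulse
#'   response, s.
#' @param delay_s Myocardial bolus-arrival delay, s.
#' @param tissue_baseline Pre-contrast myocardial signal, a.u.
#' @param noise_sigma Complex-noise sigma, a.u.; `NULL` = peak AIF / 40.
#' @param motion_amp_mm Endocardial radius excursion over one acquisition
#'   window, mm (0 = static).
#' @param temporal_filter_width Moving-average width in frames applied by
#'   the acquisition simulator (0 or 1 = none).
#' @param dt_s Frame interval (one R-R), s.
#' @param n_frames Number of dynamic frames.
#' @param seed RNG seed for the noise stream.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid = 256L, fov_mm = 340,
                           r_cavity_mm = 20, r_endo_mm = 25, r_epi_mm = 35,
                           mbf_ml_min_g = 3.5, aif = aif_params(),
                           t0_s = 4, w_s = 3, delay_s = 0,
                           tissue_baseline = 8,
                           noise_sigma = NULL, motion_amp_mm = 0,
                           temporal_filter_width = 0L,
                           dt_s = 1, n_frames = 32L, seed = 1L) {
  if (!(r_cavity_mm < r_endo_mm && r_endo_mm < r_epi_mm)) {
    abort("radii must satisfy cavity < endo < epi")
  }
  if (r_epi_mm > fov_mm / 2) abort("epicardial radius exceeds half the FOV")
  if (!is.null(noise_sigma) && noise_sigma < 0) {
    abort("noise_sigma must be nonnegative")
  }
  if (is.null(noise_sigma)) {
    pk <- max(gamma_variate_aif(seq(0, (n_frames - 1) * dt_s, by = dt_s),
                                aif)$si)
    noise_sigma <- pk / 40
  }
  structure(
    list(grid = as.integer(grid), fov_mm = fov_mm,
         r_cavity_mm = r_cavity_mm, r_endo_mm = r_endo_mm,
         r_epi_mm = r_epi_mm, mbf_ml_min_g = mbf_ml_min_g, aif = aif,
         t0_s = t0_s, w_s = w_s, delay_s = delay_s,
         tissue_baseline = tissue_baseline, noise_sigma = noise_sigma,
         motion_amp_mm = motion_amp_mm,
         temporal_filter_width = as.integer(temporal_filter_width),
         dt_s = dt_s, n_frames = as.integer(n_frames),
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Ideal AIF and myocardial curves for a phantom configuration
#'
#' Generates the ground-truth curve pair: the gamma-variate blood-pool
#' curve and the myocardial curve obtained by convolving it with the Fermi
#' impulse response at the configured flow.
#'
#' @param cfg A [phantom_config()].
#' @return A list with `aif` and `myo` [si_curve()] tibbles, plus the
#'   generating `fermi` model.
#' @export
phantom_curves <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  t_s <- seq(0, by = cfg$dt_s, length.out = cfg$n_frames)
  aif <- gamma_variate_aif(t_s, cfg$aif)
  f <- fermi_model_from_mbf(cfg$mbf_ml_min_g, cfg$t0_s, cfg$w_s, cfg$delay_s)
  irf <- fermi_irf(t_s - t_s[1], f)
  myo <- tissue_curve(aif, irf, dt = cfg$dt_s, baseline = cfg$tissue_baseline)
  list(aif = aif, myo = myo, fermi = f)
}

# distance-from-centre map (mm) for a square grid
radius_map <- function(n, spacing_mm) {
  pc <- pixel_centers(n, n, c(spacing_mm, spacing_mm))
  sqrt(outer(pc$y^2, pc$x^2, `+`))
}

# one noiseless phantom frame at given blood/myo intensities and endo radius
phantom_frame <- function(r_mm, blood_si, myo_si, r_endo, r_epi) {
  img <- matrix(0, nrow(r_mm), ncol(r_mm))
  img[r_mm <= r_endo] <- blood_si
  img[r_mm > r_endo & r_mm <= r_epi] <- myo_si
  img
}

# circle polygon in mm coordinates
circle_polygon <- function(r_mm, n_vertices = 720L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(r_mm * cos(th), r_mm * sin(th))
}

#' Render the ideal (pre-acquisition) phantom series
#'
#' Builds the concentric-disc series frame by frame: blood-disc pixels
#' follow the AIF, annulus pixels follow the myocardial curve, background is
#' zero. Returns exact ROI geometry alongside: endo/epi contours, the
#' conservative blood-pool ROI mask (`r_cavity_mm` disc) and the exact
#' cavity/annulus masks used for construction.
#'
#' @param cfg A [phantom_config()].
#' @param aif,myo Optional [si_curve()]s overriding [phantom_curves()].
#' @return A list: `series` ([dynamic_series()], carrying the phantom
#'   definition as attribute `"phantom"`), `rois` ([roi_set()]), and exact
#'   logical `masks` (`cavity`, `annulus`).
#' @export
render_series <- function(cfg, aif = NULL, myo = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (is.null(aif) || is.null(myo)) {
    pc <- phantom_curves(cfg)
    if (is.null(aif)) aif <- pc$aif
    if (is.null(myo)) myo <- pc$myo
  }
  if (nrow(aif) != nrow(myo) || any(aif$t_s != myo$t_s)) {
    abort("aif and myo curves must share one time grid")
  }
  n <- cfg$grid
  spacing <- cfg$fov_mm / n
  r <- radius_map(n, spacing)
  cavity <- r <= cfg$r_cavity_mm
  blood <- r <= cfg$r_endo_mm
  annulus <- r > cfg$r_endo_mm & r <= cfg$r_epi_mm
  frames <- array(0, dim = c(n, n, nrow(aif)))
  for (f in seq_len(nrow(aif))) {
    img <- matrix(0, n, n)
    img[blood] <- aif$si[f]
    img[annulus] <- myo$si[f]
    frames[, , f] <- img
  }
  series <- dynamic_series(frames, pixel_spacing_mm = spacing,
                           frame_times_s = aif$t_s, fov_mm = cfg$fov_mm)
  attr(series, "phantom") <- list(cfg = cfg, aif = aif, myo = myo)
  rois <- roi_set(
    endo = circle_polygon(cfg$r_endo_mm),
    epi = circle_polygon(cfg$r_epi_mm),
    blood_pool = cavity
  )
  list(series = series, rois = rois, masks = list(cavity = cavity,
                                                  annulus = annulus))
}

# 2-D fftshift / inverse
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2)),
    c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2))]
}
ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 - floor(n1 / 2) + 1):n1, 1:(n1 - floor(n1 / 2))),
    c((n2 - floor(n2 / 2) + 1):n2, 1:(n2 - floor(n2 / 2)))]
}

# indices of the central m lines of an n-line centred spectrum
central_lines <- function(n, m) {
  dc <- floor(n / 2) + 1L
  (dc - floor(m / 2)):(dc + ceiling(m / 2) - 1L)
}

# truncate k-space of one image to the central m x m block (zero-filled)
kspace_truncate <- function(img, m) {
  n <- nrow(img)
  if (m >= n) return(img + 0i)
  K <- fftshift2(fft(img))
  keep <- central_lines(n, m)
  K2 <- matrix(0i, n, n)
  K2[keep, keep] <- K[keep, keep]
  fft(ifftshift2(K2), inverse = TRUE) / (n * n)
}

#' Simulate image acquisition of an ideal series
#'
#' Applies, per frame and in order: (i) optional cardiac motion during the
#' acquisition window — each phase-encode line is taken from the k-space of
#' a phantom instance whose endocardial radius moves linearly by
#' `motion_amp_mm` over `acq_window_ms`; (ii) k-space truncation to the
#' central `acq_matrix` x `acq_matrix` block, zero-filled back to the
#' reconstruction matrix (the origin of Gibbs-ringing dark rims); then
#' (iii) an optional moving-average temporal filter across frames (a stand-in
#' for the temporal smoothing a spatio-temporal reconstruction can
#' introduce); and (iv) complex Gaussian noise of the configured sigma,
#' after which the magnitude is taken (Rician noise).
#'
#' @param ideal Ideal series from [render_series()] (reconstruction-grid
#'   resolution). Motion simulation requires the phantom attribute that
#'   [render_series()] attaches.
#' @param sp One-row sequence profile tibble (see [sequence_profile()]).
#' @param cfg The [phantom_config()] (noise, motion, filter, seed).
#' @param phase_order `"linear"` or `"centric"` phase-encode line ordering
#'   used by the motion model.
#' @return A [dynamic_series()] of acquired magnitude images.
#' @export
acquire_series <- function(ideal, sp, cfg, phase_order = c("linear",
                                                           "centric")) {
  stopifnot(inherits(ideal, "dynamic_series"),
            inherits(cfg, "phantom_config"))
  phase_order <- match.arg(phase_order)
  m <- as.integer(sp$acq_matrix)
  n_rec <- as.integer(sp$recon_matrix)
  n <- dim(ideal$frames)[1]
  if (m > n_rec) abort("acq_matrix cannot exceed recon_matrix")
  if (n != n_rec) abort("ideal series grid must equal the recon matrix")
  nt <- dim(ideal$frames)[3]
  spacing <- ideal$pixel_spacing_mm[1]

  ph <- attr(ideal, "phantom")
  use_motion <- cfg$motion_amp_mm > 0
  if (use_motion && is.null(ph)) {
    abort("motion simulation needs a phantom-rendered series")
  }

  complex_frames <- vector("list", nt)
  keep <- central_lines(n, m)
  for (f in seq_len(nt)) {
    if (!use_motion) {
      complex_frames[[f]] <- kspace_truncate(ideal$frames[, , f], m)
    } else {
      # assemble phase-encode rows from moving phantom instances
      r0 <- ph$cfg$r_endo_mm
      order_idx <- switch(phase_order,
        linear = seq_len(m),
        centric = order(abs(seq_len(m) - (floor(m / 2) + 1L)))
      )
      frac <- (match(seq_len(m), order_idx) - 1) / max(m - 1, 1)
      r_mm <- radius_map(n, spacing)
      K2 <- matrix(0i, n, n)
      blood_si <- ph$aif$si[f]
      myo_si <- ph$myo$si[f]
      for (l in seq_len(m)) {
        r_endo_l <- r0 + cfg$motion_amp_mm * frac[l]
        img_l <- phantom_frame(r_mm, blood_si, myo_si, r_endo_l,
                               ph$cfg$r_epi_mm)
        Kl <- fftshift2(fft(img_l))
        K2[keep[l], keep] <- Kl[keep[l], keep]
      }
      complex_frames[[f]] <- fft(ifftshift2(K2), inverse = TRUE) / (n * n)
    }
  }

  w <- cfg$temporal_filter_width
  if (w > 1L) {
    filtered <- vector("list", nt)
    for (f in seq_len(nt)) {
      idx <- max(1L, f - floor((w - 1) / 2)):min(nt, f + ceiling((w - 1) / 2))
      filtered[[f]] <- Reduce(`+`, complex_frames[idx]) / length(idx)
    }
    complex_frames <- filtered
  }

  frames <- withr::with_seed(cfg$seed, {
    out <- array(0, dim = c(n, n, nt))
    for (f in seq_len(nt)) {
      z <- complex_frames[[f]]
      if (cfg$noise_sigma > 0) {
        z <- z + complex(real = rnorm(n * n, sd = cfg$noise_sigma),
                         imaginary = rnorm(n * n, sd = cfg$noise_sigma))
      }
      out[, , f] <- Mod(z)
    }
    out
  })
  dynamic_series(frames, pixel_spacing_mm = ideal$pixel_spacing_mm,
                 frame_times_s = ideal$frame_times_s, fov_mm = ideal$fov_mm)
}

#' One-call phantom study: render then acquire
#'
#' @param cfg A [phantom_config()].
#' @param sp Sequence profile (one-row tibble). Defaults to `kt_high` at the
#'   configured FOV.
#' @param ... Passed to [acquire_series()].
#' @return A list: `series` (acquired), `ideal`, `rois`, `masks`, `truth`
#'   (generating curves and Fermi model).
#' @export
simulate_study <- function(cfg, sp = NULL, ...) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (is.null(sp)) {
    sp <- sequence_profile("kt_high", fov_mm = cfg$fov_mm,
                           n_frames = cfg$n_frames)
  }
  rend <- render_series(cfg)
  acq <- acquire_series(rend$series, sp, cfg, ...)
  ph <- attr(rend$series, "phantom")
  list(series = acq, ideal = rend$series, rois = rend$rois,
       masks = rend$masks,
       truth = list(aif = ph$aif, myo = ph$myo,
                    fermi = fermi_model_from_mbf(cfg$mbf_ml_min_g, cfg$t0_s,
                                                 cfg$w_s, cfg$delay_s)))
}
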
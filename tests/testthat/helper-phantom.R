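# Shared fixtures: all synthetic, built in code at test time.

# small fast phantom configuration (coarse grid keeps FFTs cheap)
tiny_cfg <- function(...) {
  phantom_config(grid = 64L, noise_sigma = 0, ...)
}

# ground-truth curve pair at a given flow on a 1 s grid
truth_curves <- function(mbf = 3.5, n = 40L, dt = 1, ...) {
  cfg <- phantom_config(mbf_ml_min_g = mbf, n_frames = n, dt_s = dt, ...)
  phantom_curves(cfg)
}

# baseline-equalized AIF/tissue pair ready for fitting
equalized_pair <- function(mbf = 3.5, n = 40L, ...) {
  pc <- truth_curves(mbf, n, ...)
  list(aif = baseline_equalize(pc$aif),
       tissue = baseline_equalize(pc$myo),
       fermi = pc$fermi)
}

# independent O(n^2) discrete causal convolution (oracle)
conv_loop <- function(a, h) {
  n <- length(a)
  y <- numeric(n)
  for (k in seq_len(n)) {
    for (j in seq_len(k)) y[k] <- y[k] + a[j] * h[k - j + 1]
  }
  y
}

# exhaustive-window OLS maximal slope via lm() (oracle)
max_upslope_lm <- function(t, y, window) {
  n <- length(y)
  slopes <- vapply(seq_len(n - window + 1), function(i) {
    idx <- i:(i + window - 1)
    unname(coef(lm(y[idx] ~ t[idx]))[2])
  }, numeric(1))
  max(slopes)
}

# square annulus-style test mask helpers
ring_mask <- function(n, r_px, width_px = 1) {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`))
  d >= r_px & d < r_px + width_px
}

# static circular roi_set centred on the grid
circle_rois <- function(r_endo_mm, r_epi_mm, blood_pool = NULL) {
  roi_set(endo = firstpass:::circle_polygon(r_endo_mm),
          epi = firstpass:::circle_polygon(r_epi_mm),
          blood_pool = blood_pool)
}
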
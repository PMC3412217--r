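test_that("gamma-variate AIF is flat before arrival and peaks where calculus says", {
  p <- aif_params(amplitude = 45, t0_s = 8, alpha = 2.5, beta_s = 1.5,
                  baseline = 10)
  t <- seq(0, 40, by = 0.01)
  aif <- gamma_variate_aif(t, p)
  expect_true(all(aif$si[t <= 8] == 10))
  t_peak <- aif$t_s[which.max(aif$si)]
  expect_equal(t_peak, 8 + 2.5 * 1.5, tolerance = 0.02)
  expect_true(all(is.finite(aif$si)))
  expect_error(aif_params(alpha = -1), "positive")
})

test_that("gamma-variate area matches the closed form within 0.1%", {
  p <- aif_params(amplitude = 3, t0_s = 5, alpha = 3.2, beta_s = 2.1,
                  baseline = 7)
  t <- seq(0, 120, by = 0.005) # long tail, fine grid
  aif <- gamma_variate_aif(t, p)
  enh <- aif$si - p$baseline
  area_quad <- sum((enh[-1] + enh[-length(enh)]) / 2) * 0.005
  area_closed <- p$amplitude * gamma(p$alpha + 1) * p$beta_s^(p$alpha + 1)
  expect_equal(area_quad, area_closed, tolerance = 1e-3)
})

test_that("fermi impulse response has the stated height, step limit and monotonicity", {
  f <- fermi_model(A_per_s = 0.1, T0_s = 4, W_s = 3, delay_s = 2)
  t <- seq(0, 60, by = 0.01)
  r <- fermi_irf(t, f)
  expect_equal(r[t == 2], 0.1 / (1 + exp(-4 / 3)))
  expect_true(all(r[t < 2] == 0))
  expect_true(all(diff(r[t >= 2]) <= 1e-12)) # nonincreasing after delay

  # W -> 0: a plateau of height A until T0 past the delay, then zero
  fs <- fermi_model(0.1, T0_s = 4, W_s = 1e-9, delay_s = 0)
  rs <- fermi_irf(c(0, 2, 3.9, 4.1, 10), fs)
  expect_equal(rs, c(0.1, 0.1, 0.1, 0, 0), tolerance = 1e-12)

  expect_error(fermi_model(0.1, W_s = 0), "positive")
})

test_that("tissue_curve is the rectangle-rule causal convolution", {
  pc <- truth_curves(mbf = 2)
  aif <- pc$aif
  dt <- 1
  n <- nrow(aif)

  # identity kernel: unit spike 1/dt in the first bin returns the
  # baseline-subtracted AIF
  spike <- c(1 / dt, rep(0, n - 1))
  out <- tissue_curve(aif, spike, dt = dt)
  expect_equal(out$si, aif$si - mean(aif$si[aif$is_baseline]),
               tolerance = 1e-12)

  # rectangular AIF x constant IRF: linear ramp of slope h * A
  rect <- si_curve(0:19, c(rep(0, 3), rep(5, 17)))
  ramp <- tissue_curve(rect, rep(0.2, 20), dt = 1)
  expect_equal(diff(ramp$si[4:20]), rep(5 * 0.2, 16), tolerance = 1e-12)

  # arbitrary inputs equal the O(n^2) double loop
  withr::with_seed(7, {
    a <- si_curve(0:29, runif(30, 0, 10))
    h <- runif(30)
    got <- tissue_curve(a, h, dt = 0.8)$si
    expect_equal(got, conv_loop(a$si, h) * 0.8, tolerance = 1e-10)
  })

  expect_error(tissue_curve(aif, rep(1, 5)), "same grid")
})

test_that("rendered phantom frames follow the generating curves exactly", {
  cfg <- tiny_cfg()
  rend <- render_series(cfg)
  ph <- attr(rend$series, "phantom")
  cav <- rend$masks$cavity
  ann <- rend$masks$annulus
  cavity_means <- vapply(seq_len(n_frames(rend$series)),
                         function(f) mean(rend$series$frames[, , f][cav]),
                         numeric(1))
  expect_identical(cavity_means, ph$aif$si)
  expect_false(any(cav & ann)) # masks partition

  # annulus pixel area matches the analytic ring area within one pixel ring
  px_area <- prod(rend$series$pixel_spacing_mm)
  a_true <- pi * (cfg$r_epi_mm^2 - cfg$r_endo_mm^2)
  ring <- 2 * pi * (cfg$r_epi_mm + cfg$r_endo_mm) *
    rend$series$pixel_spacing_mm[1]
  expect_lt(abs(sum(ann) * px_area - a_true), ring)

  expect_error(phantom_config(r_epi_mm = 200, fov_mm = 340), "FOV")
  expect_error(phantom_config(r_cavity_mm = 30, r_endo_mm = 25), "radii")
})

test_that("identity acquisition reproduces the ideal series", {
  cfg <- tiny_cfg()
  rend <- render_series(cfg)
  sp <- tibble::tibble(name = "id", acq_matrix = 64L, recon_matrix = 64L)
  acq <- acquire_series(rend$series, sp, cfg)
  expect_equal(acq$frames, rend$series$frames, tolerance = 1e-10)
  bad <- tibble::tibble(name = "bad", acq_matrix = 128L, recon_matrix = 64L)
  expect_error(acquire_series(rend$series, bad, cfg), "exceed")
})

test_that("k-space truncation of an edge matches a brute-force Dirichlet oracle", {
  n <- 64L
  m <- 32L
  profile <- rep(0, n)
  profile[21:44] <- 100 # sharp bar along x, constant along y
  img <- matrix(profile, n, n, byrow = TRUE)
  ideal <- dynamic_series(array(img, c(n, n, 1)), 1, 0)
  cfg <- tiny_cfg()
  sp <- tibble::tibble(name = "t", acq_matrix = m, recon_matrix = n)
  acq <- acquire_series(ideal, sp, cfg)
  got <- acq$frames[1, , 1]

  # oracle: direct DFT-sum convolution with the truncation kernel
  kept <- -floor(m / 2):(ceiling(m / 2) - 1)
  D <- vapply(0:(n - 1), function(d) {
    sum(exp(2i * pi * kept * d / n)) / n
  }, complex(1))
  oracle <- Mod(vapply(seq_len(n) - 1L, function(j) {
    sum(profile * D[((j - (seq_len(n) - 1L)) %% n) + 1L])
  }, complex(1)))

  expect_equal(got, oracle, tolerance = 1e-8)

  # first undershoot beside the left edge: same pixel, amplitude within 5%
  inside <- 21:32
  expect_equal(which.min(got[inside]), which.min(oracle[inside]))
  dip_got <- 100 - min(got[inside])
  dip_oracle <- 100 - min(oracle[inside])
  expect_lt(abs(dip_got - dip_oracle) / dip_oracle, 0.05)
  expect_gt(dip_got, 0) # truncation does ring
})

test_that("magnitude noise follows the Rayleigh mean on zero signal", {
  n <- 64L
  zero <- dynamic_series(array(0, c(n, n, 2)), 1, 0:1)
  cfg <- phantom_config(grid = n, noise_sigma = 3, seed = 11)
  sp <- tibble::tibble(name = "id", acq_matrix = n, recon_matrix = n)
  acq <- acquire_series(zero, sp, cfg)
  expect_equal(mean(acq$frames), 3 * sqrt(pi / 2), tolerance = 0.03)
})

test_that("truncated k-space never gains energy and acquisition is seed-deterministic", {
  withr::with_seed(3, {
    img <- matrix(runif(64 * 64), 64, 64)
  })
  full <- fft(img)
  trunc <- fft(firstpass:::kspace_truncate(img, 24L))
  expect_lte(sum(Mod(trunc)^2), sum(Mod(full)^2) * (1 + 1e-12))

  cfg <- phantom_config(grid = 64, n_frames = 8, seed = 5)
  rend <- render_series(cfg)
  sp <- tibble::tibble(name = "t", acq_matrix = 48L, recon_matrix = 64L)
  a1 <- acquire_series(rend$series, sp, cfg)
  a2 <- acquire_series(rend$series, sp, cfg)
  expect_identical(a1$frames, a2$frames)
})

test_that("temporal filtering monotonically blunts the measured AIF upslope", {
  slopes <- vapply(c(0L, 3L, 5L), function(w) {
    cfg <- tiny_cfg(temporal_filter_width = w)
    rend <- render_series(cfg)
    sp <- tibble::tibble(name = "id", acq_matrix = 64L, recon_matrix = 64L)
    acq <- acquire_series(rend$series, sp, cfg)
    bp <- vapply(seq_len(n_frames(acq)),
                 function(f) mean(acq$frames[, , f][rend$rois$blood_pool]),
                 numeric(1))
    max_upslope(si_curve(acq$frame_times_s, bp), window = 3)
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
})

test_that("acquisition-window motion blurs the endocardial edge", {
  cfg_m <- tiny_cfg(motion_amp_mm = 4, n_frames = 4)
  rend <- render_series(cfg_m)
  sp <- tibble::tibble(name = "t", acq_matrix = 32L, recon_matrix = 64L)
  moving <- acquire_series(rend$series, sp, cfg_m)
  cfg_0 <- tiny_cfg(motion_amp_mm = 0, n_frames = 4)
  static <- acquire_series(render_series(cfg_0)$series, sp, cfg_0)
  expect_false(isTRUE(all.equal(moving$frames, static$frames)))
  # motion needs the phantom definition attached
  bare <- dynamic_series(rend$series$frames, rend$series$pixel_spacing_mm,
                         rend$series$frame_times_s)
  expect_error(acquire_series(bare, sp, cfg_m), "phantom")
})
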
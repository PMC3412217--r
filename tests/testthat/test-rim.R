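# synthetic study with a known hypointense band: myocardium at 100 with
# pixel noise sd 1 on two baseline frames, then a contrast frame whose
# subendocardial band sits k SDs below the remote myocardium
banded_study <- function(k = 3, n = 64L, spacing = 1.5) {
  r_endo <- 15; r_epi <- 30
  r <- firstpass:::radius_map(n, spacing)
  myo <- r > r_endo & r <= r_epi
  band <- r > r_endo & r <= r_endo + 4 # inner ~27% of the wall
  frames <- array(0, c(n, n, 3))
  withr::with_seed(31, {
    for (f in 1:2) {
      img <- matrix(0, n, n)
      img[myo] <- 100 + rnorm(sum(myo), sd = 1)
      frames[, , f] <- img
    }
  })
  img <- matrix(0, n, n)
  img[myo] <- 100
  img[band] <- 100 - k * 1
  frames[, , 3] <- img
  list(
    series = dynamic_series(frames, spacing, 0:2),
    rois = circle_rois(r_endo, r_epi),
    band = band, myo = myo
  )
}

test_that("uniform myocardium yields empty rim masks", {
  st <- banded_study(k = 0)
  masks <- detect_rim(st$series, st$rois, search_frames = 3L,
                      baseline_frames = 1:2)
  expect_false(any(masks[[3]]))
  expect_equal(rim_duration(masks), 0)
})

test_that("a constructed band 3 SD below remote is detected exactly", {
  st <- banded_study(k = 3)
  masks <- detect_rim(st$series, st$rois, search_frames = 3L,
                      baseline_frames = 1:2)
  expect_identical(masks[[3]], st$band)
})

test_that("detection requires myocardial pixels", {
  st <- banded_study()
  bad <- circle_rois(1, 1.01)
  expect_error(detect_rim(st$series, bad, search_frames = 3L,
                          baseline_frames = 1:2), "myocardial")
})

test_that("rim thickness measures radial extent in mm", {
  n <- 64L
  rois <- circle_rois(10, 40)

  one_px <- ring_mask(n, 15, 1)
  th1 <- rim_thickness(one_px, rois, spacing_mm = 1.33)
  expect_equal(as.numeric(th1), 1.33)

  two_px <- ring_mask(n, 12, 2)
  th2 <- rim_thickness(two_px, rois, spacing_mm = 2.66)
  expect_equal(as.numeric(th2), 5.32)

  empty <- matrix(FALSE, n, n)
  th0 <- rim_thickness(empty, rois, 1.33)
  expect_equal(as.numeric(th0), 0)
  expect_equal(attr(th0, "flag"), "empty")
})

test_that("thickness in pixels times spacing equals thickness in mm exactly", {
  withr::with_seed(55, {
    n <- 48L
    rois <- circle_rois(5, 30)
    for (i in 1:10) {
      mask <- ring_mask(n, runif(1, 6, 16), sample(1:3, 1))
      t1 <- as.numeric(rim_thickness(mask, rois, spacing_mm = 1))
      t2 <- as.numeric(rim_thickness(mask, rois, spacing_mm = 2.5))
      expect_equal(t2, 2.5 * t1, tolerance = 1e-12)
    }
  })
})

test_that("thickness matches an independent angle-binned radial-span oracle", {
  # oracle: group mask pixels by angular sectors about the grid centre and
  # take the widest per-sector radial span of pixel-centre radii, floored
  # to whole one-pixel shells
  oracle_thickness <- function(mask, spacing) {
    n <- nrow(mask)
    ctr <- (n + 1) / 2
    px <- which(mask, arr.ind = TRUE)
    dx <- px[, 2] - ctr
    dy <- px[, 1] - ctr
    r <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx) %% (2 * pi)
    bins <- floor(ang / (2 * pi / 24)) # 15 deg: radial stacks share a bin
    spans <- tapply(r, bins, function(s) floor(diff(range(s)) + 1e-9) + 1)
    max(spans) * spacing
  }
  withr::with_seed(77, {
    n <- 40L
    rois <- circle_rois(4, 25)
    for (i in 1:8) {
      mask <- ring_mask(n, runif(1, 5, 12), sample(1:2, 1))
      got <- as.numeric(rim_thickness(mask, rois, spacing_mm = 2))
      want <- oracle_thickness(mask, 2)
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("rim extent is the rim share of myocardial area", {
  n <- 96L
  spacing <- 1
  rois <- circle_rois(15, 30)
  r <- firstpass:::radius_map(n, spacing)
  myo <- r > 15 & r <= 30

  expect_equal(rim_extent(myo, rois, spacing), 100, tolerance = 2)
  expect_equal(rim_extent(matrix(FALSE, n, n), rois, spacing), 0)

  pc <- firstpass:::pixel_centers(n, n, c(spacing, spacing))
  upper <- matrix(rep(pc$y, n), n, n) < 0
  expect_equal(rim_extent(myo & upper, rois, spacing), 50, tolerance = 3)

  expect_error(rim_extent(myo, circle_rois(1, 1.01), spacing), "myocardium")
})

test_that("rim duration counts frames with any surviving rim", {
  masks <- rep(list(matrix(FALSE, 8, 8)), 20)
  on <- matrix(FALSE, 8, 8); on[3:5, 3] <- TRUE
  for (f in 3:13) masks[[f]] <- on
  expect_equal(rim_duration(masks), 11)
  expect_equal(rim_duration(rep(list(NULL), 5)), 0)
})

test_that("small components are discarded at 4-connectivity", {
  m <- matrix(FALSE, 12, 12)
  m[2, 2] <- m[3, 3] <- TRUE      # two diagonal singletons: not connected
  m[8, 2:5] <- TRUE               # one 4-pixel component
  out <- firstpass:::filter_small_components(m, 3L)
  expect_equal(sum(out), 4)
  expect_true(all(out[8, 2:5]))
})

test_that("the Gibbs rim abuts the endocardial border where 1-D theory rings", {
  cfg <- phantom_config(noise_sigma = 0, n_frames = 16)
  rend <- render_series(cfg)
  sp <- tibble::tibble(name = "t", acq_matrix = 128L, recon_matrix = 256L)
  acq <- acquire_series(rend$series, sp, cfg)
  masks <- detect_rim(acq, rend$rois)
  areas <- vapply(masks, function(m) if (is.null(m)) 0L else sum(m),
                  integer(1))
  pf <- which.max(areas)
  expect_gt(areas[pf], 0)

  # radial position of detected rim pixels: first ringing lobe inside the
  # endocardial edge, i.e. within ~one acquired-resolution width of it
  r <- firstpass:::radius_map(256, acq$pixel_spacing_mm[1])
  rim_r <- r[masks[[pf]]]
  acq_res <- cfg$fov_mm / 128
  expect_gt(min(rim_r), cfg$r_endo_mm - 0.5 * acq$pixel_spacing_mm[1])
  expect_lt(min(rim_r), cfg$r_endo_mm + acq_res)

  # 1-D oracle: truncated step profile's first undershoot sits within one
  # acquired-resolution width of the edge too
  n <- 256L
  profile <- rep(0, n)
  edge_px <- which(r[129, ] <= cfg$r_endo_mm)
  profile[edge_px[1]:edge_px[length(edge_px)]] <- 1
  kept <- -64:63
  D <- vapply(0:(n - 1), function(d) sum(exp(2i * pi * kept * d / n)) / n,
              complex(1))
  trunc <- Re(vapply(seq_len(n) - 1L, function(j) {
    sum(profile * D[((j - (seq_len(n) - 1L)) %% n) + 1L])
  }, complex(1)))
  right_of_edge <- (edge_px[length(edge_px)] + 1):(edge_px[length(edge_px)] + 8)
  undershoot_px <- right_of_edge[which.min(trunc[right_of_edge])]
  undershoot_mm <- r[129, undershoot_px]
  expect_lt(abs(min(rim_r) - undershoot_mm), acq_res)
})

test_that("measure_rim reports a consistent one-row summary", {
  cfg <- phantom_config(noise_sigma = 0, n_frames = 16)
  rend <- render_series(cfg)
  sp <- tibble::tibble(name = "t", acq_matrix = 128L, recon_matrix = 256L)
  acq <- acquire_series(rend$series, sp, cfg)
  res <- measure_rim(acq, rend$rois)
  expect_equal(nrow(res), 1)
  expect_gt(res$thickness_mm, 0)
  expect_true(res$extent_pct > 0 && res$extent_pct < 100)
  # duration equals an independent per-frame re-detection count
  masks <- detect_rim(acq, rend$rois)
  expect_equal(res$duration_frames, rim_duration(masks))
  # extent is invariant to global intensity scaling
  acq2 <- dynamic_series(acq$frames * 4, acq$pixel_spacing_mm,
                         acq$frame_times_s)
  res2 <- measure_rim(acq2, rend$rois)
  expect_equal(res2$extent_pct, res$extent_pct)
})
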
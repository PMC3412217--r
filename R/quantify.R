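#' Maximal upslope of a signal-intensity curve
#'
#' Slides a linear fit of `window` consecutive samples along the curve and
#' returns the largest ordinary-least-squares slope. A five-point window is
#' the convention for myocardial curves; three points for the LV blood
#' pool, whose upslope is much shorter.
#'
#' @param c An [si_curve()] on a uniform grid.
#' @param window Number of points per fit, between 2 and the curve length.
#' @return Maximal OLS slope in a.u./s.
#' @examples
#' c <- si_curve(0:9, c(0, 0, 1, 3, 6, 10, 14, 18, 20, 21))
#' max_upslope(c, window = 5) # 3.8
#' @export
max_upslope <- function(c, window = 5L) {
  assert_si_curve(c)
  n <- nrow(c)
  window <- as.integer(window)
  if (window < 2L) abort("window must be at least 2")
  if (window > n) abort("window exceeds curve length")
  dt <- grid_dt(c$t_s)
  x <- (seq_len(window) - (window + 1) / 2) * dt # centred abscissa
  sxx <- sum(x^2)
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    y <- c$si[i:(i + window - 1L)]
    sum(x * y) / sxx # y need not be centred: sum(x) = 0
  }, numeric(1))
  max(slopes)
}

#' Semiquantitative upslope analysis of one perfusion study
#'
#' Computes the maximal upslope of each myocardial segment curve (five-point
#' fit), their mean, the LV blood-pool maximal upslope (three-point fit),
#' and the AIF-normalized mean slope — the per-study half of the myocardial
#' perfusion reserve index.
#'
#' @param curves Long tibble from [extract_si_curves()] (segments +
#'   `blood_pool`).
#' @param myo_window,aif_window Linear-fit lengths. Defaults 5 and 3.
#' @return An object of class `upslope_result`.
#' @export
upslope_analysis <- function(curves, myo_window = 5L, aif_window = 3L) {
  regions <- unique(curves$region)
  segs <- sort(regions[grepl("^segment_", regions)])
  if (!length(segs)) abort("curves contain no myocardial segments")
  if (!"blood_pool" %in% regions) abort("curves contain no blood_pool")
  seg_slopes <- vapply(
    segs, function(r) max_upslope(curve_pluck(curves, r), myo_window),
    numeric(1)
  )
  aif_slope <- max_upslope(curve_pluck(curves, "blood_pool"), aif_window)
  structure(
    list(
      segment_slopes = seg_slopes,
      mean_myo_slope = mean(seg_slopes),
      aif_slope = aif_slope,
      normalized_slope = mean(seg_slopes) / aif_slope
    ),
    class = "upslope_result"
  )
}

#' @export
print.upslope_result <- function(x, ...) {
  cat(sprintf(
    "<upslope_result> mean myocardial slope %.4g, AIF slope %.4g, normalized %.4g\n",
    x$mean_myo_slope, x$aif_slope, x$normalized_slope
  ))
  invisible(x)
}

#' @rdname upslope_analysis
#' @param x An `upslope_result`.
#' @param ... Unused.
#' @export
tidy.upslope_result <- function(x, ...) {
  tibble(
    term = c(names(x$segment_slopes), "mean_myo", "aif", "normalized"),
    slope = c(unname(x$segment_slopes), x$mean_myo_slope, x$aif_slope,
              x$normalized_slope)
  )
}

#' Myocardial perfusion reserve index from upslope results
#'
#' MPRI is the stress-to-rest ratio of AIF-normalized mean myocardial
#' upslopes: `(stress myo / stress AIF) / (rest myo / rest AIF)`.
#'
#' @param stress,rest `upslope_result` objects from [upslope_analysis()].
#' @return MPRI, unitless.
#' @export
mpri <- function(stress, rest) {
  stopifnot(inherits(stress, "upslope_result"),
            inherits(rest, "upslope_result"))
  if (stress$aif_slope <= 0 || rest$aif_slope <= 0) {
    abort("AIF maximal upslope must be positive in both states")
  }
  stress$normalized_slope / rest$normalized_slope
}

# shift a vector right by k frames, zero-padding at the front
shift_right <- function(x, k) {
  if (k <= 0L) return(x)
  c(rep(0, k), x[seq_len(length(x) - k)])
}

# sum of squared residuals of a Fermi fit at fixed integer delay
fermi_ssr <- function(par, a, y, t0grid, dt, widx, delay_frames) {
  f <- fermi_model(par[1], par[2], par[3])
  pred <- causal_convolve(shift_right(a, delay_frames),
                          fermi_irf(t0grid, f)) * dt
  sum((y[widx] - pred[widx])^2)
}

fermi_residual_fun <- function(a, y, t0grid, dt, widx, delay_frames) {
  a_sh <- shift_right(a, delay_frames)
  function(par) {
    f <- fermi_model(max(par[1], 0), max(par[2], 0), max(par[3], 1e-3))
    pred <- causal_convolve(a_sh, fermi_irf(t0grid, f)) * dt
    y[widx] - pred[widx]
  }
}

#' Estimate the LV-to-myocardium bolus delay
#'
#' Grid-searches integer frame shifts of the AIF over `[0, max_delay_s]`
#' and keeps the delay minimizing the residual of a quick preliminary Fermi
#' fit; ties resolve to the smallest delay. Degenerate (flat) input returns
#' 0 with attribute `flag = "degenerate"`.
#'
#' @param aif,tissue Baseline-equalized [si_curve()]s on one grid.
#' @param max_delay_s Largest delay searched, s. Default 5.
#' @param window First-pass window list; default from
#'   [first_pass_window()] on the AIF.
#' @return Delay in seconds (a multiple of the frame interval).
#' @export
estimate_delay <- function(aif, tissue, max_delay_s = 5, window = NULL) {
  assert_si_curve(aif, "aif"); assert_si_curve(tissue, "tissue")
  if (nrow(aif) != nrow(tissue)) abort("curves must share one grid")
  dt <- grid_dt(aif$t_s)
  if (max(aif$si) <= 0 || max(abs(tissue$si)) == 0) {
    out <- 0
    attr(out, "flag") <- "degenerate"
    warn("degenerate curves: returning delay 0")
    return(out)
  }
  if (is.null(window)) window <- first_pass_window(aif)
  # widen the fit window by the candidate shift so late samples still
  # constrain the fit
  k_max <- max(floor(max_delay_s / dt), 0L)
  widx <- window$start:min(nrow(aif), window$end + k_max)
  t0grid <- aif$t_s - aif$t_s[1]
  start <- c(A = 0.05, T0 = 4, W = 3)
  ssr <- vapply(0:max(k_max, 0L), function(k) {
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = start,
      fn = fermi_residual_fun(aif$si, tissue$si, t0grid, dt, widx, k),
      lower = c(0, 0, 0.1), upper = c(20, 30, 20),
      control = minpack.lm::nls.lm.control(maxiter = 60)
    )), silent = TRUE)
    if (inherits(fit, "try-error")) Inf else fit$deviance
  }, numeric(1))
  (which.min(ssr) - 1L) * dt
}

#' Fermi-constrained deconvolution of a myocardial curve
#'
#' Fits the three Fermi impulse-response parameters (amplitude `A`,
#' shoulder `T0`, width `W`) by bounded nonlinear least squares so that the
#' AIF convolved with the Fermi kernel reproduces the myocardial curve over
#' the first-pass window only. Absolute myocardial blood flow is read off
#' as the initial height of the fitted impulse response:
#' `MBF = 60 * A / (1 + exp(-T0 / W))` ml/min/g (signal proportional to
#' concentration, tissue density 1 g/ml).
#'
#' Bounds are A in \[0, 20\] 1/s, T0 in \[0, 30\] s, W in \[0.1, 20\] s;
#' three deterministic multi-starts guard against local minima.
#'
#' @param aif,tissue Baseline-equalized [si_curve()]s on one uniform grid.
#' @param window First-pass window (list with `start`, `end`); default
#'   computed from the AIF.
#' @param delay_s LV-to-myocardium delay, rounded to whole frames; default
#'   0. See [estimate_delay()].
#' @param starts Matrix of multi-start parameter rows `(A, T0, W)`.
#' @param ftol Least-squares convergence tolerance. Default 1e-8.
#' @return An object of class `fermi_fit`: fitted [fermi_model()], MBF,
#'   residual RMS over the window, the window, and the data with fitted
#'   values.
#' @export
fit_fermi <- function(aif, tissue, window = NULL, delay_s = 0,
                      starts = NULL, ftol = 1e-8) {
  assert_si_curve(aif, "aif"); assert_si_curve(tissue, "tissue")
  if (nrow(aif) != nrow(tissue) || any(aif$t_s != tissue$t_s)) {
    abort("aif and tissue must share one time grid")
  }
  dt <- grid_dt(aif$t_s)
  if (is.null(window)) window <- first_pass_window(aif)
  widx <- window$start:window$end
  t0grid <- aif$t_s - aif$t_s[1]
  delay_frames <- as.integer(round(delay_s / dt))
  if (is.null(starts)) {
    starts <- rbind(c(0.02, 2, 1), c(0.1, 4, 3), c(0.5, 8, 6))
  }
  res_fun <- fermi_residual_fun(aif$si, tissue$si, t0grid, dt, widx,
                                delay_frames)
  best <- NULL
  diagnostics <- character(0)
  for (s in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = setNames(starts[s, ], c("A", "T0", "W")), fn = res_fun,
      lower = c(0, 0, 0.1), upper = c(20, 30, 20),
      control = minpack.lm::nls.lm.control(ftol = ftol, ptol = ftol,
                                           maxiter = 200)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) {
      diagnostics <- c(diagnostics, as.character(fit))
      next
    }
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    abort(c("Fermi fit failed to converge from any start", diagnostics))
  }
  par <- coef(best)
  flag <- NULL
  if (par[["A"]] < 0) { # unreachable under bounds; kept as a guard
    par[["A"]] <- 0
    flag <- "negative amplitude clipped to 0"
  }
  f <- fermi_model(par[["A"]], par[["T0"]], par[["W"]],
                   delay_s = delay_frames * dt)
  pred <- causal_convolve(shift_right(aif$si, delay_frames),
                          fermi_irf(t0grid, fermi_model(par[["A"]],
                                                        par[["T0"]],
                                                        par[["W"]]))) * dt
  structure(
    list(
      fermi = f,
      mbf_ml_min_g = fermi_mbf(f),
      residual_rms = sqrt(best$deviance / length(widx)),
      window = window,
      delay_s = delay_frames * dt,
      flag = flag,
      data = tibble(t_s = aif$t_s, aif = aif$si, tissue = tissue$si,
                    fitted = pred,
                    in_window = seq_along(t0grid) %in% widx)
    ),
    class = "fermi_fit"
  )
}

#' @export
print.fermi_fit <- function(x, ...) {
  cat(sprintf(
    "<fermi_fit> MBF %.3f ml/min/g (A %.4g /s, T0 %.3g s, W %.3g s, delay %.3g s), RMS %.3g\n",
    x$mbf_ml_min_g, x$fermi$A_per_s, x$fermi$T0_s, x$fermi$W_s, x$delay_s,
    x$residual_rms
  ))
  invisible(x)
}

#' @rdname fit_fermi
#' @param x A `fermi_fit`.
#' @param ... Unused.
#' @export
tidy.fermi_fit <- function(x, ...) {
  tibble(
    term = c("A_per_s", "T0_s", "W_s", "delay_s"),
    estimate = c(x$fermi$A_per_s, x$fermi$T0_s, x$fermi$W_s, x$delay_s)
  )
}

#' @rdname fit_fermi
#' @export
glance.fermi_fit <- function(x, ...) {
  tibble(
    mbf_ml_min_g = x$mbf_ml_min_g,
    residual_rms = x$residual_rms,
    delay_s = x$delay_s,
    window_start = x$window$start,
    window_end = x$window$end
  )
}

#' Myocardial perfusion reserve
#'
#' @param stress_mbf,rest_mbf Absolute flows in ml/min/g; rest must be
#'   positive.
#' @return MPR = stress / rest, unitless.
#' @export
mpr <- function(stress_mbf, rest_mbf) {
  if (rest_mbf <= 0) abort("rest MBF must be positive")
  stress_mbf / rest_mbf
}

#' Quantify one study's curves end to end
#'
#' Convenience wrapper: detects baseline frames from the blood-pool curve,
#' equalizes baselines, locates the first pass, estimates the delay and
#' runs the Fermi deconvolution on the mean myocardial curve (mean of the
#' six segment curves), as the in vivo analysis did globally over the
#' myocardial circumference.
#'
#' @param curves Long tibble from [extract_si_curves()].
#' @param estimate_delay_flag Estimate the LV-myocardium delay (else 0).
#' @return A `fermi_fit`.
#' @export
quantify_study <- function(curves, estimate_delay_flag = FALSE) {
  aif_raw <- curve_pluck(curves, "blood_pool")
  bl <- detect_baseline_frames(aif_raw)
  if (length(bl) < 2L) abort("fewer than 2 pre-contrast baseline frames")
  aif <- baseline_equalize(set_baseline_frames(aif_raw, bl))
  segs <- sort(unique(curves$region[grepl("^segment_", curves$region)]))
  myo_si <- rowMeans(vapply(segs,
                            function(r) curve_pluck(curves, r)$si,
                            numeric(nrow(aif))))
  myo <- baseline_equalize(si_curve(aif$t_s, myo_si, bl))
  window <- first_pass_window(aif)
  delay <- if (estimate_delay_flag) {
    estimate_delay(aif, myo, window = window)
  } else 0
  fit_fermi(aif, myo, window = window, delay_s = delay)
}
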
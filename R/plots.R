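#' Plot frames of a dynamic series
#'
#' @param object A [dynamic_series()].
#' @param frames Frame indices to show (default: 6 spread over the series).
#' @param ... Unused.
#' @return A ggplot object (grey raster montage).
#' @export
autoplot.dynamic_series <- function(object, frames = NULL, ...) {
  nt <- dim(object$frames)[3]
  if (is.null(frames)) {
    frames <- unique(round(seq(1, nt, length.out = min(6, nt))))
  }
  pc <- pixel_centers(dim(object$frames)[1], dim(object$frames)[2],
                      object$pixel_spacing_mm)
  df <- purrr::map(frames, function(f) {
    tibble(
      x_mm = rep(pc$x, each = length(pc$y)),
      y_mm = rep(pc$y, length(pc$x)),
      si = as.vector(object$frames[, , f]),
      frame = f
    )
  })
  df <- bind_rows(df)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$si)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~frame, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "SI (a.u.)")
}

#' Plot extracted signal-intensity curves
#'
#' @param curves Long tibble from [extract_si_curves()].
#' @return A ggplot object (one line per region).
#' @export
plot_si_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$t_s, .data$si,
                                       colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "signal intensity (a.u.)",
                  colour = NULL)
}

#' Plot a Fermi deconvolution fit
#'
#' Shows the AIF, the myocardial data and the fitted forward model, with
#' the first-pass fit window shaded.
#'
#' @param object A `fermi_fit` from [fit_fermi()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fermi_fit <- function(object, ...) {
  d <- object$data
  w <- d$t_s[range(which(d$in_window))]
  long <- tidyr::pivot_longer(d, c("aif", "tissue", "fitted"),
                              names_to = "curve", values_to = "si")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_s, .data$si,
                                     colour = .data$curve)) +
    ggplot2::annotate("rect", xmin = w[1], xmax = w[2], ymin = -Inf,
                      ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = "signal (a.u., baseline-equalized)",
      colour = NULL,
      subtitle = sprintf("MBF %.2f ml/min/g", object$mbf_ml_min_g)
    )
}

#' Plot rim thickness against acquired matrix
#'
#' @param experiment Tibble from [rim_matrix_experiment()].
#' @return A ggplot object.
#' @export
plot_rim_experiment <- function(experiment) {
  long <- tidyr::pivot_longer(experiment, c("thickness_mm", "extent_pct"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$acq_matrix, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "acquired matrix (lines)", y = NULL)
}
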
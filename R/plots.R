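#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an image plane of a cube
#'
#' @param object A [cars_cube()].
#' @param wavenumber Wavenumber of the plane to show (default: the
#'   channel nearest 2933 cm-1, else the middle channel).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cars_cube <- function(object, wavenumber = NULL, ...) {
  if (is.null(wavenumber)) {
    wavenumber <- if (max(object$axis) >= 2933) 2933 else stats::median(object$axis)
  }
  sl <- cube_slice(object, wavenumber)
  df <- tibble::tibble(y = rep(seq_len(nrow(sl)), ncol(sl)),
                       x = rep(seq_len(ncol(sl)), each = nrow(sl)),
                       intensity = as.vector(sl))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Intensity at %.0f cm-1",
                                  attr(sl, "wavenumber")),
                  x = NULL, y = NULL, fill = "a.u.") +
    ggplot2::theme_minimal()
}

#' Plot an amide I fit with its components
#'
#' @param object An `amide_fit` from [fit_amide_band()].
#' @param ... Unused.
#' @return A ggplot showing the data, the three fitted Gaussian
#'   components and their sum over the fit window.
#' @export
autoplot.amide_fit <- function(object, ...) {
  axis <- object$axis
  comp <- object$components
  bands <- purrr::pmap_dfr(comp, function(role, center, fwhm, amplitude, area) {
    tibble::tibble(role = role, wavenumber = axis,
                   intensity = gaussian_band(axis, amplitude, center, fwhm))
  })
  total <- dplyr::summarise(dplyr::group_by(bands, .data$wavenumber),
                            intensity = sum(.data$intensity))
  obs <- tibble::tibble(wavenumber = axis, intensity = object$intensity)
  ggplot2::ggplot(obs, ggplot2::aes(.data$wavenumber, .data$intensity)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = bands,
                       ggplot2::aes(color = .data$role), linewidth = 0.5) +
    ggplot2::geom_line(data = total, linewidth = 0.8) +
    ggplot2::labs(x = "Raman shift (cm-1)", y = "Im[chi3] (a.u.)",
                  color = "component") +
    ggplot2::theme_minimal()
}

#' Plot the senescence indicator maps
#'
#' Ratio map in \[0, 1\] with invalid pixels in dark purple, and the
#' subtraction map on a diverging scale clipped at +/- 3 perinuclear
#' standard deviations (blue: beta-sheet-rich, red: alpha-helix-rich).
#'
#' @param object An [indicator_maps()] result.
#' @param which `"ratio"` or `"subtraction"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.indicator_maps <- function(object, which = c("ratio", "subtraction"),
                                    ...) {
  which <- match.arg(which)
  df <- tidy.indicator_maps(object)
  if (which == "ratio") {
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$ratio)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                    na.value = "#2D004B") +
      ggplot2::coord_fixed() +
      ggplot2::labs(x = NULL, y = NULL, fill = "g2/(g1+g2)") +
      ggplot2::theme_minimal()
  } else {
    lim <- 3 * object$scale
    df$clipped <- pmin(pmax(df$subtraction, -lim), lim)
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$clipped)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_gradient2(low = "#B2182B", mid = "white",
                                    high = "#2166AC", limits = c(-lim, lim)) +
      ggplot2::coord_fixed() +
      ggplot2::labs(x = NULL, y = NULL, fill = "g2-g1") +
      ggplot2::theme_minimal()
  }
}

#' Plot per-cell nucleolar ratios by class
#'
#' @param records Classified records from [classify_cells()].
#' @return A ggplot boxplot with jittered per-cell points.
#' @export
plot_cell_records <- function(records) {
  df <- records[records$has_nucleus &
                  is.finite(records$largest_nucleolus_mean_ratio), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$phenotype_class,
                                   .data$largest_nucleolus_mean_ratio)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "largest-nucleolus mean g2/(g1+g2)") +
    ggplot2::theme_minimal()
}

#' Plot the size-ratio regression
#'
#' @param x A [size_ratio_regression()] result.
#' @param records The records the regression was fitted on.
#' @return A ggplot scatter with the fitted line.
#' @export
plot_size_ratio <- function(x, records) {
  df <- records[is.finite(records$largest_nucleolus_size) &
                  is.finite(records$largest_nucleolus_mean_ratio), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$largest_nucleolus_size,
                                   .data$largest_nucleolus_mean_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = x$intercept, slope = x$slope,
                         color = "firebrick") +
    ggplot2::labs(x = "largest nucleolus size (pixels)",
                  y = "mean g2/(g1+g2)",
                  subtitle = sprintf("slope %.2g, p = %.3g", x$slope,
                                     x$p_value)) +
    ggplot2::theme_minimal()
}
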
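#' Asymmetrically reweighted penalized least-squares baseline
#'
#' Iterative smooth-baseline estimator: a second-difference (Whittaker)
#' penalty with logistic weights that are asymmetrically re-estimated
#' each pass so that peak regions are progressively down-weighted while
#' baseline regions keep full weight. Terminates when the relative
#' change of the weight vector falls below `ratio_tol` or at `max_iter`.
#'
#' @param y Numeric spectrum (length >= 8, finite).
#' @param lam Smoothness penalty (> 0); larger is smoother. Default 1e5.
#' @param ratio_tol Convergence tolerance on the weight change (1e-6).
#' @param max_iter Iteration cap (100).
#' @return List with `baseline`, `corrected` (`y - baseline`, exactly),
#'   `weights` (final, in (0, 1\]), `iterations`, `converged`.
#' @export
arpls <- function(y, lam = 1e5, ratio_tol = 1e-6, max_iter = 100) {
  if (any(!is.finite(y))) stop("arpls: inputs must be finite")
  if (lam <= 0) stop("arpls: lam must be > 0")
  if (length(y) < 8) stop("arpls: spectrum length must be >= 8")
  r <- .arpls_engine(as.numeric(y), lam, ratio_tol, as.integer(max_iter))
  list(baseline = r$baseline, corrected = y - r$baseline,
       weights = r$weights, iterations = r$iterations,
       converged = r$converged)
}

#' arPLS baseline correction of a spectrum tibble
#'
#' Data-frame interface to [arpls()].
#'
#' @param spectrum Tibble with columns `wavenumber`, `intensity`.
#' @inheritParams arpls
#' @return Tibble with columns `wavenumber`, `intensity`, `baseline`,
#'   `corrected`; attributes `iterations`, `converged`.
#' @export
arpls_baseline <- function(spectrum, lam = 1e5, ratio_tol = 1e-6,
                           max_iter = 100) {
  r <- arpls(spectrum$intensity, lam = lam, ratio_tol = ratio_tol,
             max_iter = max_iter)
  out <- tibble::tibble(wavenumber = spectrum$wavenumber,
                        intensity = spectrum$intensity,
                        baseline = r$baseline, corrected = r$corrected)
  attr(out, "iterations") <- r$iterations
  attr(out, "converged") <- r$converged
  out
}

#' Apply arPLS baseline correction to every pixel of a cube
#'
#' @param cube A [cars_cube()] (Im domain).
#' @inheritParams arpls
#' @return The cube with every pixel spectrum baseline-corrected.
#' @export
arpls_cube <- function(cube, lam = 1e5, ratio_tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(cube, "cars_cube"))
  d <- dim(cube$values)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  out <- .arpls_cube_engine(flat, lam, ratio_tol, as.integer(max_iter))
  cube$values <- array(out, d)
  cube
}

#' Calibrate the wavenumber axis from reference peaks
#'
#' Least-squares polynomial mapping of detector pixel index to
#' wavenumber, anchored on reference peaks of known position (in
#' practice reconstructed reference spectra such as ethanol and
#' polystyrene; here any peak list).
#'
#' @param observed_peak_pixels Detector pixel positions of the peaks.
#' @param reference_wavenumbers Known wavenumbers (cm-1), same length.
#' @param order Polynomial order, 1 or 2; needs >= order + 1 peaks.
#' @param detector_range Pixel range over which monotonicity is checked
#'   (default: the span of the observed peaks).
#' @return Object of class `calibration_map`: list with `coefficients`
#'   (intercept first), `residuals`, `peaks` tibble, and `order`.
#'   Use [predict()] to map pixel indices to wavenumbers.
#' @examples
#' cal <- calibrate_axis(c(100, 200), c(1000, 2000), order = 1)
#' predict(cal, 150)  # 1500
#' @export
calibrate_axis <- function(observed_peak_pixels, reference_wavenumbers,
                           order = 1, detector_range = NULL) {
  if (length(observed_peak_pixels) != length(reference_wavenumbers)) {
    stop("calibrate_axis: peak pixel and wavenumber counts must match")
  }
  if (!order %in% c(1, 2)) stop("calibrate_axis: order must be 1 or 2")
  n <- length(observed_peak_pixels)
  if (n < order + 1) {
    stop("calibrate_axis: need at least order + 1 reference peaks")
  }
  X <- stats::poly(observed_peak_pixels, degree = order, raw = TRUE,
                   simple = TRUE)
  fit <- stats::lm.fit(cbind(1, X), reference_wavenumbers)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  if (is.null(detector_range)) detector_range <- range(observed_peak_pixels)
  px <- seq(detector_range[1], detector_range[2], length.out = 256)
  deriv <- cf[2] + if (order == 2) 2 * cf[3] * px else 0
  if (any(deriv <= 0)) {
    stop("calibrate_axis: fitted pixel-to-wavenumber map is not strictly increasing")
  }
  structure(list(coefficients = unname(cf), residuals = unname(fit$residuals),
                 order = order,
                 peaks = tibble::tibble(pixel = observed_peak_pixels,
                                        wavenumber = reference_wavenumbers)),
            class = "calibration_map")
}

#' @export
predict.calibration_map <- function(object, newdata, ...) {
  px <- if (is.list(newdata)) newdata[[1]] else newdata
  cf <- object$coefficients
  out <- cf[1] + cf[2] * px
  if (object$order == 2) out <- out + cf[3] * px^2
  out
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("<calibration_map> order %d, %d reference peaks, max |residual| %.3g cm-1\n",
              x$order, nrow(x$peaks), max(abs(x$residuals))))
  invisible(x)
}

#' Subtract the mean outside-cell spectrum (baseline stage 1)
#'
#' Averages the spectra of all pixels outside the cells and subtracts
#' that mean spectrum from every pixel of the cube.
#'
#' @param cube A [cars_cube()].
#' @param outside_mask Logical matrix (TRUE outside cells), matching the
#'   cube's spatial dimensions, non-empty.
#' @return The corrected cube.
#' @export
subtract_outside_baseline <- function(cube, outside_mask) {
  stopifnot(inherits(cube, "cars_cube"))
  if (!all(dim(outside_mask) == dim(cube$values)[1:2])) {
    stop("subtract_outside_baseline: mask shape must match cube spatial dims")
  }
  if (!any(outside_mask)) stop("subtract_outside_baseline: empty outside mask")
  d <- dim(cube$values)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  b <- colMeans(flat[as.vector(outside_mask), , drop = FALSE])
  cube$values <- array(sweep(flat, 2, b, "-"), d)
  cube
}

#' Automatic outside-cell mask
#'
#' Thresholds the CH-region (2933 cm-1) intensity image at its Otsu
#' level; the low class is taken as outside the cells.
#'
#' @param intensity_2933 Non-negative intensity matrix.
#' @return Logical matrix, TRUE outside cells.
#' @export
outside_mask_auto <- function(intensity_2933) {
  rng <- range(intensity_2933)
  if (diff(rng) <= 0) stop("outside_mask_auto: image has no contrast")
  norm <- (intensity_2933 - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  norm < th
}

#' Remove the water band at 1640 cm-1
#'
#' `component_subtract` jointly fits the three amide-region components
#' plus one broad band fixed at 1640 cm-1 (amplitude >= 0, width chosen
#' from a grid) by non-negative least squares, and subtracts only the
#' water component; `off` returns the input unchanged.
#'
#' @param spectrum Tibble with columns `wavenumber`, `intensity`.
#' @param mode `"component_subtract"` or `"off"`.
#' @param model A [band_model()] for the non-water components.
#' @param width_grid Candidate water FWHMs (cm-1).
#' @return The spectrum tibble with `intensity` water-free; attributes
#'   `water_amplitude`, `water_fwhm`.
#' @export
remove_water_band <- function(spectrum, mode = c("component_subtract", "off"),
                              model = band_model(),
                              width_grid = seq(50, 140, by = 10)) {
  mode <- match.arg(mode)
  if (mode == "off") return(spectrum)
  axis <- spectrum$wavenumber
  if (min(axis) > 1640 || max(axis) < 1640) {
    stop("remove_water_band: axis must cover 1640 cm-1")
  }
  y <- spectrum$intensity
  Xamide <- sapply(seq_len(nrow(model)), function(i) {
    gaussian_band(axis, 1, model$center[i], model$fwhm[i])
  })
  best <- NULL
  for (w in width_grid) {
    X <- cbind(Xamide, gaussian_band(axis, 1, 1640, w))
    fit <- pracma::lsqnonneg(X, y)
    if (is.null(best) || fit$resid.norm < best$rss) {
      best <- list(rss = fit$resid.norm, amp = fit$x[ncol(X)], fwhm = w)
    }
  }
  out <- spectrum
  out$intensity <- y - gaussian_band(axis, best$amp, 1640, best$fwhm)
  attr(out, "water_amplitude") <- best$amp
  attr(out, "water_fwhm") <- best$fwhm
  out
}
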
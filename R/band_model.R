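#' Amide I band model
#'
#' The amide I region of an Im\[chi3\] (Raman-equivalent) spectrum is
#' decomposed into three Gaussian components with fixed roles:
#' component 0, the purine ring skeleton of DNA and RNA (1570 cm-1,
#' FWHM 15 cm-1); component 1, amide I of the protein alpha-helix
#' structure plus cis C=C of unsaturated lipids (1650 cm-1, FWHM
#' 30 cm-1); and component 2, amide I of the protein beta-sheet
#' structure (1667 cm-1, FWHM 22 cm-1). The decomposition is performed
#' over the 1540-1740 cm-1 fit window. Linewidths follow the FWHM
#' convention throughout.
#'
#' @param centers Numeric length-3, component peak wavenumbers (cm-1).
#' @param fwhm Numeric length-3, component linewidths as FWHM (cm-1).
#' @param window Numeric length-2, fit window (cm-1), lower < upper.
#' @param roles Character length-3, component role labels.
#'
#' @return An object of class `band_model`: a tibble with one row per
#'   component (`role`, `center`, `fwhm`) and attributes `window` and
#'   `linewidth_convention`.
#' @examples
#' band_model()
#' @export
band_model <- function(centers = c(1570, 1650, 1667),
                       fwhm = c(15, 30, 22),
                       window = c(1540, 1740),
                       roles = c("purine", "alpha_helix_lipid", "beta_sheet")) {
  stopifnot(length(centers) == length(fwhm), length(roles) == length(centers))
  if (any(fwhm <= 0)) stop("band_model: linewidths must be > 0")
  if (!(window[1] < window[2])) stop("band_model: window lower must be < upper")
  if (any(centers <= window[1] | centers >= window[2])) {
    stop("band_model: all component centers must lie inside the fit window")
  }
  out <- tibble::tibble(role = roles, center = centers, fwhm = fwhm)
  attr(out, "window") <- window
  attr(out, "linewidth_convention") <- "fwhm"
  class(out) <- c("band_model", class(out))
  out
}

#' Evaluate a Gaussian band
#'
#' `G(nu) = amplitude * exp(-4 ln 2 (nu - center)^2 / fwhm^2)`, so that
#' `G(center) = amplitude` and `G(center +/- fwhm/2) = amplitude / 2`.
#'
#' @param axis Wavenumber grid (cm-1).
#' @param amplitude Peak amplitude.
#' @param center Peak wavenumber (cm-1).
#' @param fwhm Full width at half maximum (cm-1), > 0.
#' @return Numeric vector of band values on `axis`.
#' @export
gaussian_band <- function(axis, amplitude, center, fwhm) {
  if (fwhm <= 0) stop("gaussian_band: fwhm must be > 0")
  amplitude * exp(-4 * log(2) * (axis - center)^2 / fwhm^2)
}

#' Integrated band intensity of a Gaussian component
#'
#' Analytic area of the FWHM-parameterised Gaussian:
#' `g = amplitude * fwhm * sqrt(pi / (4 ln 2))`.
#'
#' @inheritParams gaussian_band
#' @return The integrated band intensity (intensity * cm-1).
#' @export
integrated_intensity <- function(amplitude, fwhm) {
  if (any(fwhm <= 0)) stop("integrated_intensity: fwhm must be > 0")
  amplitude * fwhm * sqrt(pi / (4 * log(2)))
}

#' Peak amplitude of a Gaussian component of given area
#'
#' Inverse of [integrated_intensity()].
#'
#' @param area Integrated band intensity.
#' @param fwhm Full width at half maximum (cm-1), > 0.
#' @return Peak amplitude.
#' @export
amplitude_from_area <- function(area, fwhm) {
  if (any(fwhm <= 0)) stop("amplitude_from_area: fwhm must be > 0")
  area / (fwhm * sqrt(pi / (4 * log(2))))
}

#' @export
print.band_model <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("<band_model> %d Gaussian components, window %g-%g cm-1 (FWHM convention)\n",
              nrow(x), w[1], w[2]))
  print(tibble::as_tibble(x))
  invisible(x)
}
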
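#' Hyperspectral cube container
#'
#' A `cars_cube` wraps a numeric `y x x x wavenumber` array with its
#' wavenumber axis (cm-1), pixel size (um/pixel) and acquisition mode
#' (`"im_domain"` for Im\[chi3\] cubes, `"chi3_domain"` for raw CARS
#' intensity cubes awaiting phase retrieval).
#'
#' @param values Numeric 3-D array, dimensions `c(ny, nx, n_wavenumber)`.
#' @param axis Strictly increasing wavenumber axis (cm-1), length equal
#'   to `dim(values)[3]`.
#' @param pixel_size Pixel size in um/pixel (> 0).
#' @param mode `"im_domain"` or `"chi3_domain"`.
#' @param meta Optional named list of metadata (seed, config hash, ...).
#' @return An object of class `cars_cube`.
#' @export
cars_cube <- function(values, axis, pixel_size = 0.5,
                      mode = c("im_domain", "chi3_domain"), meta = list()) {
  mode <- match.arg(mode)
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (length(axis) != dim(values)[3]) {
    stop("cars_cube: axis length must equal the spectral dimension")
  }
  if (any(diff(axis) <= 0)) stop("cars_cube: axis must be strictly increasing")
  if (pixel_size <= 0) stop("cars_cube: pixel_size must be > 0")
  structure(list(values = values, axis = as.numeric(axis),
                 pixel_size = pixel_size, mode = mode, meta = meta),
            class = "cars_cube")
}

#' @export
print.cars_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<cars_cube> %dx%d px (%.2g um/px), %d channels %g-%g cm-1, mode %s\n",
              d[1], d[2], x$pixel_size, d[3], min(x$axis), max(x$axis), x$mode))
  invisible(x)
}

#' @export
dim.cars_cube <- function(x) dim(x$values)

#' Extract the image plane nearest a wavenumber
#'
#' @param cube A [cars_cube()].
#' @param wavenumber Target wavenumber (cm-1).
#' @return Numeric matrix `ny x nx`, with attribute `wavenumber` giving
#'   the channel actually used.
#' @export
cube_slice <- function(cube, wavenumber) {
  stopifnot(inherits(cube, "cars_cube"))
  i <- which.min(abs(cube$axis - wavenumber))
  out <- cube$values[, , i]
  attr(out, "wavenumber") <- cube$axis[i]
  out
}

#' Extract one pixel spectrum as a tibble
#'
#' @param cube A [cars_cube()].
#' @param y,x Pixel indices (row, column).
#' @return Tibble with columns `wavenumber`, `intensity`.
#' @export
cube_spectrum <- function(cube, y, x) {
  stopifnot(inherits(cube, "cars_cube"))
  tibble::tibble(wavenumber = cube$axis, intensity = cube$values[y, x, ])
}

#' Mean spectrum over a pixel mask
#'
#' @param cube A [cars_cube()].
#' @param mask Logical matrix matching the cube's spatial dimensions.
#' @return Tibble with columns `wavenumber`, `intensity` (mask mean).
#' @export
cube_region_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "cars_cube"))
  if (!all(dim(mask) == dim(cube$values)[1:2])) {
    stop("cube_region_spectrum: mask shape must match cube spatial dims")
  }
  if (!any(mask)) stop("cube_region_spectrum: empty mask")
  flat <- matrix(cube$values, prod(dim(cube$values)[1:2]), dim(cube$values)[3])
  tibble::tibble(wavenumber = cube$axis,
                 intensity = colMeans(flat[as.vector(mask), , drop = FALSE]))
}

# apply a function spectrum -> spectrum over every pixel (vectorised over
# pixels where possible by the caller; this is the generic fallback)
cube_apply <- function(cube, f, ...) {
  d <- dim(cube$values)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  out <- t(apply(flat, 1, f, ...))
  cube$values <- array(out, d)
  cube
}
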
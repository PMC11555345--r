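#' Write a hyperspectral cube to disk
#'
#' Binary little-endian float64 array plus a JSON sidecar
#' (`<path>.json`) recording `axis_cm1`, `pixel_size_um`, `axes_order`
#' (always written canonical `"y,x,nu"`), `dim`, `mode` and any cube
#' metadata (seed, config hash).
#'
#' @param cube A [cars_cube()].
#' @param path Output path for the binary array (e.g. `"cube.bin"`);
#'   the sidecar is written next to it as `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "cars_cube"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(cube$values), con, size = 8, endian = "little")
  sidecar <- list(axis_cm1 = cube$axis, pixel_size_um = cube$pixel_size,
                  axes_order = "y,x,nu", dim = dim(cube$values),
                  mode = cube$mode, meta = cube$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a hyperspectral cube from disk
#'
#' Reads the binary array and its JSON sidecar, validates consistency
#' and returns the cube in canonical `y,x,nu` order whatever order the
#' sidecar declares.
#'
#' @param path Path given to [write_cube()].
#' @return A [cars_cube()].
#' @export
read_cube <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("read_cube: missing sidecar file '", sidecar_path, "'")
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("axis_cm1", "pixel_size_um", "axes_order", "dim", "mode")) {
    if (is.null(sc[[f]])) stop("read_cube: sidecar missing field '", f, "'")
  }
  dm <- as.integer(sc$dim)
  if (length(dm) != 3) stop("read_cube: sidecar field 'dim' must have length 3")
  order_names <- strsplit(sc$axes_order, ",")[[1]]
  if (!setequal(order_names, c("y", "x", "nu"))) {
    stop("read_cube: sidecar field 'axes_order' must be a permutation of y,x,nu")
  }
  n <- prod(dm)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n + 1, size = 8, endian = "little")
  if (length(vals) != n) {
    stop("read_cube: binary size does not match sidecar field 'dim'")
  }
  arr <- array(vals, dm)
  perm <- match(c("y", "x", "nu"), order_names)
  arr <- aperm(arr, perm)
  if (length(sc$axis_cm1) != dim(arr)[3]) {
    stop("read_cube: sidecar field 'axis_cm1' length does not match the spectral dimension")
  }
  meta <- if (is.null(sc$meta)) list() else as.list(sc$meta)
  cars_cube(arr, as.numeric(sc$axis_cm1), pixel_size = sc$pixel_size_um,
            mode = sc$mode, meta = meta)
}

#' Write a label or intensity image
#'
#' Single-channel TIFF (float) via the `tiff` package when available,
#' else PNG (values scaled to the 0-1 range). Label codes: 0 background,
#' 1 cytoplasm, 2 nucleoplasm, 3 nucleolus.
#'
#' @param image Numeric matrix.
#' @param path Output path (`.tif`/`.tiff` or `.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("write_image: the 'tiff' package is required for TIFF output")
    }
    tiff::writeTIFF(image / max(1, max(abs(image))), path,
                    bits.per.sample = 32L)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("write_image: the 'png' package is required for PNG output")
    }
    rng <- range(image)
    norm <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
    png::writePNG(norm, path)
  } else {
    stop("write_image: unsupported extension '", ext, "'")
  }
  invisible(path)
}
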
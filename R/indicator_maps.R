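#' Ratio indicator map g2 / (g1 + g2)
#'
#' Per-pixel occupancy of the beta-sheet component among the two
#' protein components. Pixels whose ratio is `mask_threshold`
#' (default 1e-19, the display rule for near-zero ratios) or less, or
#' whose denominator `g1 + g2` is zero, are flagged invalid and
#' excluded from statistics (rendered as the reserved dark-purple
#' color).
#'
#' @param fitmaps An `amide_fit_maps` from [fit_cube()].
#' @param mask_threshold Ratio values at or below this are invalid.
#' @return Matrix of ratios in \[0, 1\] (NA on invalid pixels) with
#'   attributes `valid` (logical matrix) and `mask_threshold`.
#' @export
ratio_map <- function(fitmaps, mask_threshold = 1e-19) {
  stopifnot(inherits(fitmaps, "amide_fit_maps"))
  if (any(fitmaps$g1 < 0) || any(fitmaps$g2 < 0)) {
    stop("ratio_map: negative integrated intensities violate the fit contract")
  }
  den <- fitmaps$g1 + fitmaps$g2
  r <- fitmaps$g2 / den
  valid <- den > 0 & r > mask_threshold & fitmaps$converged
  r[!valid] <- NA_real_
  attr(r, "valid") <- valid
  attr(r, "mask_threshold") <- mask_threshold
  r
}

#' Subtraction indicator map g2 - g1
#'
#' Signed per-pixel difference of the beta-sheet and alpha-helix
#' integrated intensities (area units). The display scale is the
#' standard deviation of the values in a perinuclear scaling region
#' (`scaling_region_mask`); rendered maps use diverging limits of
#' +/- 3 scale units, blue toward high component 2 (beta) and red
#' toward high component 1 (alpha). Stored values are unscaled.
#'
#' @param fitmaps An `amide_fit_maps` from [fit_cube()].
#' @param scaling_region_mask Logical matrix, non-empty; typically a
#'   ring around the nuclei, see [perinuclear_ring()].
#' @return Matrix `g2 - g1` with attributes `scale` (SD in the scaling
#'   region; 1 as unit fallback when the SD is 0) and `scaling_region`.
#' @export
subtraction_map <- function(fitmaps, scaling_region_mask) {
  stopifnot(inherits(fitmaps, "amide_fit_maps"))
  if (missing(scaling_region_mask) || !any(scaling_region_mask)) {
    stop("subtraction_map: scaling region mask must be non-empty")
  }
  s <- fitmaps$g2 - fitmaps$g1
  sc <- stats::sd(s[scaling_region_mask])
  if (!is.finite(sc) || sc == 0) sc <- 1  # unit fallback for degenerate regions
  attr(s, "scale") <- sc
  attr(s, "scaling_region") <- scaling_region_mask
  s
}

#' Perinuclear scaling ring
#'
#' Morphological ring of `width` pixels immediately outside the nucleus
#' mask (nucleoplasm plus nucleoli), used as the scaling region for the
#' subtraction map.
#'
#' @param label Integer region matrix (0 bg, 1 cytoplasm, 2 nucleoplasm,
#'   3 nucleolus), e.g. a phantom label image or segmentation output.
#' @param width Ring width in pixels (default 2).
#' @return Logical matrix.
#' @export
perinuclear_ring <- function(label, width = 2) {
  nuc <- label >= 2
  kern <- EBImage::makeBrush(2 * width + 1, shape = "box")
  dil <- EBImage::dilate(EBImage::Image(nuc * 1), kern) > 0.5
  ring <- as.matrix(dil) & !nuc
  if (!any(ring)) ring <- label == 1  # fall back to the whole cytoplasm
  ring
}

#' Compute both senescence indicator maps
#'
#' Convenience wrapper producing the ratio map and the subtraction map
#' with its perinuclear display scale.
#'
#' @param fitmaps An `amide_fit_maps` from [fit_cube()].
#' @param label Region label matrix for the scaling ring.
#' @param mask_threshold Passed to [ratio_map()].
#' @param ring_width Passed to [perinuclear_ring()].
#' @return Object of class `indicator_maps`: list with `ratio`,
#'   `valid`, `subtraction`, `scale`, `mask_threshold`.
#' @export
indicator_maps <- function(fitmaps, label, mask_threshold = 1e-19,
                           ring_width = 2) {
  r <- ratio_map(fitmaps, mask_threshold)
  ring <- perinuclear_ring(label, ring_width)
  s <- subtraction_map(fitmaps, ring)
  structure(list(ratio = unclass_attr(r), valid = attr(r, "valid"),
                 subtraction = unclass_attr(s), scale = attr(s, "scale"),
                 mask_threshold = mask_threshold),
            class = "indicator_maps")
}

# strip helper attributes so plain matrices are stored
unclass_attr <- function(m) {
  attributes(m) <- attributes(m)["dim"]
  m
}

#' @export
print.indicator_maps <- function(x, ...) {
  cat(sprintf("<indicator_maps> %dx%d px, %d invalid, subtraction scale %.4g\n",
              nrow(x$ratio), ncol(x$ratio), sum(!x$valid), x$scale))
  invisible(x)
}
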
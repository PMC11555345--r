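#' Segment cellular regions from a CH-band intensity image
#'
#' Multi-level intensity thresholding of the 2933 cm-1 image into four
#' ordered classes (background < cytoplasm < nucleus < nucleolus) by
#' k-means with deterministic quantile-based initial centers, followed
#' by 4-connected component labeling. Nucleolus components that do not
#' lie against nucleoplasm are demoted (to nucleoplasm when adjacent to
#' a nucleus, else to cytoplasm) so every nucleolus lies within a
#' nucleus.
#'
#' @param intensity_2933 Non-negative 2-D intensity matrix.
#' @param n_levels Number of intensity classes (default 4).
#' @return List with `region` (integer matrix, codes 0-3), `cells`
#'   (4-connected labeling of all cell pixels), `nuclei` (labeling of
#'   nucleus pixels, codes >= 2), `nucleoli` (labeling of nucleolus
#'   pixels), and `thresholds` (class mean intensities).
#' @export
segment_regions <- function(intensity_2933, n_levels = 4) {
  img <- intensity_2933
  if (any(img < 0)) stop("segment_regions: image must be non-negative")
  vals <- unique(as.vector(img))
  if (length(vals) < 2) {
    if (all(img == 0)) {
      # an empty field of view is all background, not an error
      z <- matrix(0L, nrow(img), ncol(img))
      return(list(region = z, cells = z, nuclei = z, nucleoli = z,
                  thresholds = numeric()))
    }
    stop("segment_regions: image must contain >= 2 distinct values")
  }
  if (length(vals) <= n_levels) {
    # discrete well-separated levels: rank order maps directly to codes
    code <- match(as.vector(img), sort(vals)) - 1L
    km_centers <- sort(vals)
  } else {
    centers <- seq(min(img), max(img), length.out = n_levels)
    km <- stats::kmeans(as.vector(img), centers = matrix(centers, ncol = 1),
                        iter.max = 100)
    ord <- order(km$centers)
    code <- match(km$cluster, ord) - 1L
    km_centers <- sort(as.vector(km$centers))
  }
  region <- matrix(code, nrow(img), ncol(img))

  # constrain nucleoli to lie within nuclei
  nol_lab <- label_components(region == 3)
  if (max(nol_lab) > 0) {
    nuc_adj <- adjacency_classes(region, nol_lab)
    for (k in seq_len(max(nol_lab))) {
      if (!2 %in% nuc_adj[[k]]) {
        region[nol_lab == k] <- if (1 %in% nuc_adj[[k]]) 1L else 2L
      }
    }
  }
  list(region = region,
       cells = label_components(region >= 1),
       nuclei = label_components(region >= 2),
       nucleoli = label_components(region == 3),
       thresholds = km_centers)
}

#' 4-connected component labeling
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 background), labeled
#'   in raster order.
#' @export
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

# region codes adjacent to (4-neighborhood of) each labeled component
adjacency_classes <- function(region, labels) {
  out <- vector("list", max(labels))
  if (max(labels) == 0) return(out)
  ny <- nrow(region); nx <- ncol(region)
  shift <- function(m, dy, dx) {
    res <- matrix(NA_integer_, ny, nx)
    ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
    ok_y <- ys >= 1 & ys <= ny; ok_x <- xs >= 1 & xs <= nx
    res[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
    res
  }
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- shift(region, d[1], d[2])
    sel <- labels > 0 & !is.na(nb)
    if (!any(sel)) next
    pairs <- unique(cbind(labels[sel], nb[sel]))
    for (i in seq_len(nrow(pairs))) {
      k <- pairs[i, 1]
      out[[k]] <- union(out[[k]], pairs[i, 2])
    }
  }
  out
}
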
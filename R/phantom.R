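#' Phantom layout configuration
#'
#' Geometry for the labeled cell phantom: circular cells (cytoplasm)
#' containing one nucleus (control) or two disjoint nuclei (senescent),
#' each nucleus containing one or more circular nucleoli. Defaults give
#' a control nucleus of radius 5 px at 0.5 um/pixel (cross-sectional
#' area `pi * 5^2 * 0.25 ~ 20 um2`, well below the 118 um2 mononuclear
#' control threshold) and enlarged cells, nuclei pairs and nucleoli in
#' senescent cells.
#'
#' @param dim Image dimensions `c(ny, nx)`, each >= 64.
#' @param n_control,n_senescent Cell counts per phenotype.
#' @param cell_radius,nucleus_radius,nucleolus_radius Control-cell radii
#'   in pixels (nucleolus < nucleus < cell).
#' @param senescent_cell_radius,senescent_nucleus_radius,senescent_nucleolus_radius
#'   Senescent-cell radii in pixels; the cell must be large enough to
#'   hold two disjoint nuclei (`cell_radius >= 2 * nucleus_radius + 1`).
#' @param nucleoli_per_nucleus Nucleoli drawn in each nucleus (0 allowed).
#' @param pixel_size Pixel size in um/pixel (> 0).
#' @return A `phantom_layout` list.
#' @export
phantom_layout <- function(dim = c(96, 96), n_control = 6, n_senescent = 6,
                           cell_radius = 9, nucleus_radius = 5,
                           nucleolus_radius = 2,
                           senescent_cell_radius = 11,
                           senescent_nucleus_radius = 5,
                           senescent_nucleolus_radius = 3,
                           nucleoli_per_nucleus = 1,
                           pixel_size = 0.5) {
  stopifnot(length(dim) == 2, all(dim >= 64))
  if (n_control + n_senescent < 1) stop("phantom_layout: need at least one cell")
  if (pixel_size <= 0) stop("phantom_layout: pixel_size must be > 0")
  ok <- nucleolus_radius < nucleus_radius && nucleus_radius < cell_radius &&
    senescent_nucleolus_radius < senescent_nucleus_radius &&
    senescent_nucleus_radius < senescent_cell_radius
  if (!ok) stop("phantom_layout: need nucleolus radius < nucleus radius < cell radius")
  if (senescent_cell_radius < 2 * senescent_nucleus_radius + 1) {
    stop("phantom_layout: senescent cell radius too small for two disjoint nuclei")
  }
  structure(list(dim = dim, n_control = n_control, n_senescent = n_senescent,
                 cell_radius = cell_radius, nucleus_radius = nucleus_radius,
                 nucleolus_radius = nucleolus_radius,
                 senescent_cell_radius = senescent_cell_radius,
                 senescent_nucleus_radius = senescent_nucleus_radius,
                 senescent_nucleolus_radius = senescent_nucleolus_radius,
                 nucleoli_per_nucleus = nucleoli_per_nucleus,
                 pixel_size = pixel_size),
            class = "phantom_layout")
}

# paint a filled disc into a logical matrix
disc_mask <- function(dim, cy, cx, r) {
  yy <- matrix(seq_len(dim[1]), dim[1], dim[2])
  xx <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

#' Generate a labeled cell phantom
#'
#' Places cells on a seeded, shuffled and jittered grid (no overlaps by
#' construction) and paints region labels: 0 background, 1 cytoplasm,
#' 2 nucleoplasm, 3 nucleolus. Senescent cells receive two disjoint
#' nuclei and enlarged nucleoli; every nucleolus lies inside a nucleus
#' and every nucleus inside its cell's cytoplasm extent. Deterministic
#' for a fixed seed.
#'
#' @param layout A [phantom_layout()].
#' @param seed Integer RNG seed.
#' @return An object of class `cars_phantom`: list with `label`
#'   (integer region matrix), `cell_id` (integer cell map, 0 outside
#'   cells), `cells` (tibble: `cell_id`, `phenotype`, `cy`, `cx`,
#'   `radius`, `nuclei`), `pixel_size`, and `layout`.
#' @examples
#' ph <- make_phantom(phantom_layout(n_control = 2, n_senescent = 1), seed = 1)
#' table(ph$label)
#' @export
make_phantom <- function(layout = phantom_layout(), seed = 1) {
  stopifnot(inherits(layout, "phantom_layout"))
  dm <- layout$dim
  n <- layout$n_control + layout$n_senescent
  phen <- rep(c("control", "senescent"),
              c(layout$n_control, layout$n_senescent))
  radius <- ifelse(phen == "senescent", layout$senescent_cell_radius,
                   layout$cell_radius)
  rmax <- max(radius)
  set.seed(seed)

  # shuffled jittered grid: slots spaced >= 2*rmax+1 apart
  ncol_g <- ceiling(sqrt(n * dm[2] / dm[1]))
  nrow_g <- ceiling(n / ncol_g)
  sy <- dm[1] / nrow_g; sx <- dm[2] / ncol_g
  jit <- max(0, min(sy, sx) / 2 - rmax - 1)
  if (min(sy, sx) < 2 * rmax + 1 || sy < 2 * rmax + 2 || sx < 2 * rmax + 2) {
    stop(sprintf("make_phantom: cell %d cannot fit: image too small for %d cells of radius %d",
                 n, n, rmax))
  }
  slots <- expand.grid(gy = seq_len(nrow_g), gx = seq_len(ncol_g))
  slots <- slots[sample(nrow(slots), n), , drop = FALSE]
  centers <- cbind((slots$gy - 0.5) * sy + stats::runif(n, -jit, jit),
                   (slots$gx - 0.5) * sx + stats::runif(n, -jit, jit))
  centers[, 1] <- pmin(pmax(centers[, 1], radius + 1), dm[1] - radius - 1)
  centers[, 2] <- pmin(pmax(centers[, 2], radius + 1), dm[2] - radius - 1)

  label <- matrix(0L, dm[1], dm[2])
  cell_id <- matrix(0L, dm[1], dm[2])
  nuclei <- integer(n)
  for (i in seq_len(n)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    cyt <- disc_mask(dm, cy, cx, radius[i])
    if (any(cell_id[cyt] != 0L)) {
      stop(sprintf("make_phantom: cell %d cannot fit: overlaps a placed cell", i))
    }
    label[cyt] <- 1L
    cell_id[cyt] <- i
    if (phen[i] == "senescent") {
      rn <- layout$senescent_nucleus_radius
      nr <- layout$senescent_nucleolus_radius
      ang <- stats::runif(1, 0, pi)
      off <- min(rn + 0.75, radius[i] - rn - 0.5)
      ncent <- rbind(c(cy + off * sin(ang), cx + off * cos(ang)),
                     c(cy - off * sin(ang), cx - off * cos(ang)))
      nuclei[i] <- 2L
    } else {
      rn <- layout$nucleus_radius
      nr <- layout$nucleolus_radius
      ncent <- rbind(c(cy, cx))
      nuclei[i] <- 1L
    }
    for (k in seq_len(nrow(ncent))) {
      nuc <- disc_mask(dm, ncent[k, 1], ncent[k, 2], rn)
      label[nuc] <- 2L
      for (m in seq_len(layout$nucleoli_per_nucleus)) {
        maxoff <- max(rn - nr - 1, 0)
        oy <- stats::runif(1, -maxoff, maxoff)
        ox <- stats::runif(1, -maxoff, maxoff)
        sc <- sqrt(oy^2 + ox^2)
        if (sc > maxoff && sc > 0) { oy <- oy * maxoff / sc; ox <- ox * maxoff / sc }
        nol <- disc_mask(dm, ncent[k, 1] + oy, ncent[k, 2] + ox, nr)
        label[nol & nuc] <- 3L
      }
    }
  }
  cells <- tibble::tibble(cell_id = seq_len(n), phenotype = phen,
                          cy = centers[, 1], cx = centers[, 2],
                          radius = radius, nuclei = nuclei)
  structure(list(label = label, cell_id = cell_id, cells = cells,
                 pixel_size = layout$pixel_size, layout = layout),
            class = "cars_phantom")
}

#' @export
print.cars_phantom <- function(x, ...) {
  cat(sprintf("<cars_phantom> %dx%d px (%.2g um/px), %d cells (%d control, %d senescent)\n",
              nrow(x$label), ncol(x$label), x$pixel_size, nrow(x$cells),
              sum(x$cells$phenotype == "control"),
              sum(x$cells$phenotype != "control")))
  cat(sprintf("  region pixels: bg %d, cytoplasm %d, nucleoplasm %d, nucleolus %d\n",
              sum(x$label == 0), sum(x$label == 1), sum(x$label == 2),
              sum(x$label == 3)))
  invisible(x)
}
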
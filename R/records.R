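#' Extract per-cell nucleolar records
#'
#' For every cell: counts nuclei (4-connected components of the nucleus
#' mask within the cell), measures the largest nucleus cross-sectional
#' area (`pixel count * pixel_size^2`, um2), selects the largest
#' nucleolus (maximal pixel count, ties broken by lowest component
#' label) and averages the ratio and subtraction indicators over that
#' nucleolus' valid pixels (the cross-sectional average used to score
#' each cell). Cells without a nucleus are flagged (`has_nucleus =
#' FALSE`) and should be excluded from statistics.
#'
#' @param masks Either a [make_phantom()] phantom (ground-truth cell
#'   map) or a [segment_regions()] result (cells are then the
#'   4-connected cytoplasm components).
#' @param maps An [indicator_maps()] result.
#' @param pixel_size Pixel size in um/pixel (> 0); defaults to the
#'   phantom's when available.
#' @return Tibble with one row per cell: `cell_id`, `phenotype` (when
#'   known), `nuclei_count`, `largest_nucleus_area` (um2),
#'   `largest_nucleolus_size` (pixel count),
#'   `largest_nucleolus_mean_ratio`,
#'   `largest_nucleolus_mean_subtraction`, `has_nucleus`.
#' @export
extract_cell_records <- function(masks, maps, pixel_size = NULL) {
  stopifnot(inherits(maps, "indicator_maps"))
  if (inherits(masks, "cars_phantom")) {
    region <- masks$label
    cell_map <- masks$cell_id
    phen <- masks$cells$phenotype
    if (is.null(pixel_size)) pixel_size <- masks$pixel_size
  } else {
    region <- masks$region
    cell_map <- masks$cells
    phen <- NULL
    if (is.null(pixel_size)) {
      stop("extract_cell_records: pixel_size required with segmentation masks")
    }
  }
  if (pixel_size <= 0) stop("extract_cell_records: pixel_size must be > 0")
  if (!all(dim(region) == dim(maps$ratio))) {
    stop("extract_cell_records: mask and map shapes differ")
  }
  nuc_lab <- label_components(region >= 2)
  nol_lab <- label_components(region == 3)
  n_cells <- max(cell_map)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    in_cell <- cell_map == i
    nuc_ids <- setdiff(unique(nuc_lab[in_cell]), 0L)
    if (length(nuc_ids) == 0) {
      rows[[i]] <- tibble::tibble(
        cell_id = i, nuclei_count = 0L, largest_nucleus_area = 0,
        largest_nucleolus_size = 0L,
        largest_nucleolus_mean_ratio = NA_real_,
        largest_nucleolus_mean_subtraction = NA_real_,
        has_nucleus = FALSE)
      next
    }
    nuc_sizes <- vapply(nuc_ids, function(k) sum(nuc_lab == k & in_cell),
                        integer(1))
    nol_ids <- setdiff(unique(nol_lab[in_cell]), 0L)
    if (length(nol_ids)) {
      nol_sizes <- vapply(nol_ids, function(k) sum(nol_lab == k & in_cell),
                          integer(1))
      # largest by pixel count; ties broken by lowest component label
      best <- nol_ids[order(-nol_sizes, nol_ids)][1]
      best_size <- nol_sizes[which(nol_ids == best)]
      sel <- nol_lab == best & in_cell & maps$valid
      mr <- if (any(sel)) mean(maps$ratio[sel]) else NA_real_
      ms <- if (any(sel)) mean(maps$subtraction[sel]) else NA_real_
    } else {
      best_size <- 0L; mr <- NA_real_; ms <- NA_real_
    }
    rows[[i]] <- tibble::tibble(
      cell_id = i, nuclei_count = length(nuc_ids),
      largest_nucleus_area = max(nuc_sizes) * pixel_size^2,
      largest_nucleolus_size = as.integer(best_size),
      largest_nucleolus_mean_ratio = mr,
      largest_nucleolus_mean_subtraction = ms,
      has_nucleus = TRUE)
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(phen)) out <- dplyr::mutate(out, phenotype = phen[.data$cell_id],
                                           .after = "cell_id")
  out
}

#' Classify one cell record
#'
#' Control: exactly one nucleus with cross-sectional area strictly
#' below 118 um2. Binucleate: two or more nuclei. Large-nucleus:
#' mononuclear with area at or above 118 um2 (the boundary is
#' excluded from control by the strict inequality).
#'
#' @param record One-row data frame with `nuclei_count` and
#'   `largest_nucleus_area`.
#' @param area_threshold Control nucleus area threshold (um2).
#' @return `"control"`, `"binucleate"` or `"large_nucleus"`.
#' @export
classify_cell <- function(record, area_threshold = 118) {
  if (record$nuclei_count == 0) {
    stop("classify_cell: cell has no nucleus")
  }
  if (record$nuclei_count >= 2) return("binucleate")
  if (record$largest_nucleus_area < area_threshold) "control" else "large_nucleus"
}

#' Classify all cell records
#'
#' Adds a `phenotype_class` column by [classify_cell()]; rows with
#' `nuclei_count == 0` get `NA` and `has_nucleus = FALSE`.
#'
#' @param records Tibble from [extract_cell_records()].
#' @inheritParams classify_cell
#' @return The records tibble with `phenotype_class` appended.
#' @export
classify_cells <- function(records, area_threshold = 118) {
  cls <- vapply(seq_len(nrow(records)), function(i) {
    if (records$nuclei_count[i] == 0) return(NA_character_)
    classify_cell(records[i, ], area_threshold)
  }, character(1))
  dplyr::mutate(records, phenotype_class = cls)
}
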
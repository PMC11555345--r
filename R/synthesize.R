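#' Noise configuration for synthetic cubes
#'
#' Additive Gaussian noise with an optional intensity-proportional
#' (shot-like) variance term: the per-sample standard deviation is
#' `sqrt(sd^2 + shot_fraction * intensity * sd)` when
#' `shot_fraction > 0`, else `sd`.
#'
#' @param sd Baseline additive noise standard deviation (>= 0).
#' @param shot_fraction Weight of the intensity-proportional variance
#'   term (>= 0; 0 disables it).
#' @param baseline_amplitude Amplitude of a smooth, slowly varying
#'   spectral baseline added to every pixel (0 disables it). The
#'   baseline is a gentle quadratic in wavenumber whose strength varies
#'   smoothly across the field of view.
#' @return A `noise_config` list.
#' @export
noise_config <- function(sd = 0, shot_fraction = 0, baseline_amplitude = 0) {
  if (sd < 0 || shot_fraction < 0 || baseline_amplitude < 0) {
    stop("noise_config: all noise levels must be >= 0")
  }
  structure(list(sd = sd, shot_fraction = shot_fraction,
                 baseline_amplitude = baseline_amplitude),
            class = "noise_config")
}

# smooth quadratic baseline shape on [min(axis), max(axis)], max ~ 1
baseline_shape <- function(axis) {
  u <- (axis - min(axis)) / diff(range(axis))
  0.6 + 0.4 * u - 0.5 * (u - 0.4)^2
}

# region/phenotype lookup: list(control = list(cytoplasm=..., ...), ...)
region_names <- c("cytoplasm", "nucleoplasm", "nucleolus")

#' Synthesize a hyperspectral cube from a phantom
#'
#' Builds the per-pixel spectrum from each pixel's (phenotype, region)
#' composition. In `im_domain` mode the spectrum is the noiseless
#' composed Im\[chi3\] spectrum plus an optional smooth baseline and
#' Gaussian noise. In `chi3_domain` mode the raw CARS intensity
#' `|chiNR + sum_j A_j / (Omega_j - nu - i Gamma_j)|^2` is generated
#' from Lorentzian lines matched to the Gaussian truth in center and
#' band area, with half-widths `Gamma = FWHM/2` so FWHMs agree.
#' Ground truth (exact per-pixel g-values and region beta fractions) is
#' returned alongside. Deterministic for a fixed seed.
#'
#' @param phantom A [make_phantom()] phantom.
#' @param compositions Named list with one element per phenotype present
#'   in the phantom; each a named list of [spectral_composition()] per
#'   region (`cytoplasm`, `nucleoplasm`, `nucleolus`). Defaults to
#'   [default_compositions()] per phenotype.
#' @param axis Wavenumber axis (cm-1), strictly increasing.
#' @param noise A [noise_config()].
#' @param mode `"im_domain"` or `"chi3_domain"`.
#' @param chi_nr Nonresonant background level for `chi3_domain` mode.
#' @param seed Integer RNG seed.
#' @return List with elements `cube` (a [cars_cube()]), `truth` (list:
#'   `g0`, `g1`, `g2` matrices of exact integrated intensities, `ratio`
#'   matrix `g2/(g1+g2)`, `table` tibble of per-(phenotype, region)
#'   compositions and beta fractions), and `intensity_2933` (matrix;
#'   CH-band contrast image for segmentation, from the cube when the
#'   axis covers 2933 cm-1, else rendered from the CH weights).
#' @export
synthesize_cube <- function(phantom,
                            compositions = NULL,
                            axis = seq(1500, 1800, by = 2.5),
                            noise = noise_config(),
                            mode = c("im_domain", "chi3_domain"),
                            chi_nr = 1,
                            seed = 1) {
  stopifnot(inherits(phantom, "cars_phantom"))
  if (!mode[1] %in% c("im_domain", "chi3_domain")) {
    stop("synthesize_cube: unknown mode '", mode[1], "'")
  }
  mode <- match.arg(mode)
  if (any(diff(axis) <= 0)) stop("synthesize_cube: axis must be strictly increasing")
  phenos <- unique(phantom$cells$phenotype)
  if (is.null(compositions)) {
    compositions <- stats::setNames(lapply(phenos, default_compositions), phenos)
  }
  for (p in phenos) {
    if (is.null(compositions[[p]]) ||
        !all(region_names %in% names(compositions[[p]]))) {
      stop("synthesize_cube: missing composition for phenotype '", p, "'")
    }
  }
  ch_covered <- max(axis) >= 2933 + 3 * 55 / 2  # CH band at least half-covered
  dm <- dim(phantom$label)
  nv <- length(axis)
  set.seed(seed)

  # one spectrum per (phenotype, region); background is zero signal
  keyfor <- function(p, r) paste(p, r, sep = ".")
  specs <- list(); gtruth <- list(); truth_rows <- list()
  for (p in phenos) for (r in region_names) {
    comp <- compositions[[p]][[r]]
    comp_used <- comp
    if (!ch_covered) comp_used$ch <- 0  # CH band outside axis: keep it out of the cube
    y <- if (mode == "im_domain") {
      suppressWarnings(compose_region_spectrum(comp_used, axis)$intensity)
    } else {
      simulate_raw_cars(lorentzian_chi3_from_composition(comp_used, chi_nr), axis)$intensity
    }
    specs[[keyfor(p, r)]] <- y
    gtruth[[keyfor(p, r)]] <- c(comp$purine, comp$alpha, comp$beta)
    truth_rows[[keyfor(p, r)]] <- tibble::tibble(
      phenotype = p, region = r, g0 = comp$purine, g1 = comp$alpha,
      g2 = comp$beta, ch = comp$ch,
      beta_fraction = beta_fraction(comp))
  }

  values <- array(0, c(dm[1], dm[2], nv))
  g0 <- g1 <- g2 <- matrix(0, dm[1], dm[2])
  if (mode == "chi3_domain") {
    # background pixels carry the nonresonant intensity
    bg <- rep(chi_nr^2, nv)
    values <- array(rep(bg, each = dm[1] * dm[2]), c(dm[1], dm[2], nv))
  }
  pheno_of_cell <- phantom$cells$phenotype
  for (p in phenos) for (ri in 1:3) {
    r <- region_names[ri]
    sel <- phantom$label == ri &
      matrix(pheno_of_cell[pmax(phantom$cell_id, 1)] == p, dm[1], dm[2]) &
      phantom$cell_id > 0
    if (!any(sel)) next
    idx <- which(sel)
    y <- specs[[keyfor(p, r)]]
    for (k in seq_len(nv)) values[idx + (k - 1) * dm[1] * dm[2]] <- y[k]
    gg <- gtruth[[keyfor(p, r)]]
    g0[idx] <- gg[1]; g1[idx] <- gg[2]; g2[idx] <- gg[3]
  }

  if (noise$baseline_amplitude > 0 && mode == "im_domain") {
    shape <- baseline_shape(axis)
    yy <- matrix(seq_len(dm[1]), dm[1], dm[2]) / dm[1]
    xx <- matrix(seq_len(dm[2]), dm[1], dm[2], byrow = TRUE) / dm[2]
    field <- noise$baseline_amplitude * (0.8 + 0.2 * sin(2 * pi * yy) * cos(pi * xx))
    for (k in seq_len(nv)) {
      values[, , k] <- values[, , k] + field * shape[k]
    }
  }
  if (noise$sd > 0) {
    sdmap <- if (noise$shot_fraction > 0) {
      sqrt(noise$sd^2 + noise$shot_fraction * pmax(values, 0) * noise$sd)
    } else noise$sd
    values <- values + array(stats::rnorm(length(values), 0, 1),
                             dim(values)) * sdmap
  }

  ratio <- g2 / (g1 + g2)
  ratio[g1 + g2 <= 0] <- NA_real_
  cube <- cars_cube(values, axis, pixel_size = phantom$pixel_size, mode = mode,
                    meta = list(seed = seed, mode = mode,
                                noise = unclass(noise)))
  # CH contrast image for segmentation
  if (ch_covered) {
    i2933 <- cube_slice(cube, 2933)
  } else {
    i2933 <- matrix(0, dm[1], dm[2])
    for (p in phenos) for (ri in 1:3) {
      sel <- phantom$label == ri & phantom$cell_id > 0 &
        matrix(pheno_of_cell[pmax(phantom$cell_id, 1)] == p, dm[1], dm[2])
      if (!any(sel)) next
      comp <- compositions[[p]][[region_names[ri]]]
      i2933[sel] <- amplitude_from_area(comp$ch, 55)
    }
    if (noise$sd > 0) i2933 <- i2933 + stats::rnorm(length(i2933), 0, noise$sd)
  }
  list(cube = cube,
       truth = list(g0 = g0, g1 = g1, g2 = g2, ratio = ratio,
                    table = dplyr::bind_rows(truth_rows),
                    label = phantom$label, cell_id = phantom$cell_id,
                    cells = phantom$cells),
       intensity_2933 = i2933)
}

#' Simulate a mononuclear sweep of nucleolar sizes
#'
#' Emulates a field of naive mononuclear cells with a natural spread of
#' nucleolar sizes: nucleolus radii cycle over `radii`, and each cell's
#' nucleolar beta fraction rises linearly with radius between
#' `beta_range[1]` and `beta_range[2]` plus a per-cell Gaussian jitter
#' (ongoing senescence scales with nucleolar enlargement). Each cell is
#' synthesized, fitted and quantified through the standard pipeline
#' stages, yielding one record per cell for [size_ratio_regression()].
#'
#' @param n_cells Number of cells (default 24).
#' @param radii Nucleolus radii in pixels to cycle over.
#' @param beta_range Nucleolar beta fraction at the smallest and largest
#'   radius.
#' @param beta_jitter SD of the per-cell beta-fraction jitter.
#' @param noise A [noise_config()] for the synthesized cubes.
#' @param axis Wavenumber axis.
#' @param seed Integer seed.
#' @return Tibble of cell records (one row per cell) as from
#'   [extract_cell_records()], plus `true_beta_fraction` and
#'   `nucleolus_radius`.
#' @export
mononuclear_sweep <- function(n_cells = 24, radii = c(2, 3, 4, 5),
                              beta_range = c(0.2, 0.55),
                              beta_jitter = 0.03,
                              noise = noise_config(sd = 0.002),
                              axis = seq(1500, 1800, by = 2.5),
                              seed = 1) {
  set.seed(seed)
  r_cell <- rep_len(radii, n_cells)
  f_cell <- beta_range[1] + (beta_range[2] - beta_range[1]) *
    (r_cell - min(radii)) / max(max(radii) - min(radii), 1)
  f_cell <- pmin(pmax(f_cell + stats::rnorm(n_cells, 0, beta_jitter),
                      0.02), 0.95)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    ly <- phantom_layout(dim = c(64, 64), n_control = 1, n_senescent = 0,
                         cell_radius = 10, nucleus_radius = 7,
                         nucleolus_radius = r_cell[i])
    ph <- make_phantom(ly, seed = seed + 1000 + i)
    comps <- list(control = list(
      cytoplasm = composition_from_beta_fraction(1, 0.2, purine = 0.25),
      nucleoplasm = composition_from_beta_fraction(1.2, 0.25, purine = 0.45),
      nucleolus = composition_from_beta_fraction(1.6, f_cell[i],
                                                 purine = 0.6)))
    sim <- synthesize_cube(ph, compositions = comps, axis = axis,
                           noise = noise, seed = seed + 2000 + i)
    cube <- subtract_outside_baseline(sim$cube, ph$cell_id == 0)
    fm <- fit_cube(cube)
    maps <- indicator_maps(fm, ph$label)
    rec <- extract_cell_records(ph, maps)
    rec$cell_id <- i
    rec$true_beta_fraction <- f_cell[i]
    rec$nucleolus_radius <- r_cell[i]
    rows[[i]] <- rec
  }
  dplyr::bind_rows(rows)
}
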
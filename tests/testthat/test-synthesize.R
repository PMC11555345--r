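test_that("noiseless im_domain cubes reproduce the composed spectra exactly", {
  sc <- make_test_scene()
  ph <- sc$phantom; sim <- sc$sim
  ax <- sim$cube$axis
  comp <- default_compositions("control")$nucleolus
  comp$ch <- 0  # axis stops at 1800: the CH band is not in the cube
  expected <- compose_region_spectrum(comp, ax)$intensity
  px <- which(ph$label == 3 &
                matrix(ph$cells$phenotype[pmax(ph$cell_id, 1)] == "control",
                       nrow(ph$label), ncol(ph$label)),
              arr.ind = TRUE)[1, ]
  expect_equal(sim$cube$values[px[1], px[2], ], expected, tolerance = 1e-12)
  # background pixels are exactly zero
  bg <- which(ph$cell_id == 0, arr.ind = TRUE)[1, ]
  expect_true(all(sim$cube$values[bg[1], bg[2], ] == 0))
})

test_that("ground truth records the composition exactly across a beta sweep", {
  ph <- make_phantom(phantom_layout(n_control = 1, n_senescent = 0),
                     seed = 3)
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    comps <- list(control = list(
      cytoplasm = composition_from_beta_fraction(1, 0.2, purine = 0.25),
      nucleoplasm = composition_from_beta_fraction(1.2, 0.25, purine = 0.45),
      nucleolus = composition_from_beta_fraction(1.6, f, purine = 0.6)))
    sim <- synthesize_cube(ph, compositions = comps, seed = 5)
    r <- sim$truth$ratio[ph$label == 3]
    if (f == 0) expect_true(all(r == 0)) else expect_equal(unique(r), f)
  }
})

test_that("region-mean amide peaks sit where the phenotypes put them", {
  sc <- make_test_scene()
  ph <- sc$phantom; cube <- sc$sim$cube
  phen_map <- matrix(ph$cells$phenotype[pmax(ph$cell_id, 1)],
                     nrow(ph$label), ncol(ph$label))
  peak_of <- function(mask) {
    sp <- cube_region_spectrum(cube, mask)
    win <- sp$wavenumber >= 1540 & sp$wavenumber <= 1740
    sp$wavenumber[win][which.max(sp$intensity[win])]
  }
  expect_gt(peak_of(ph$label == 3 & phen_map == "senescent" & ph$cell_id > 0),
            1660)
  expect_lt(peak_of(ph$label == 3 & phen_map == "control" & ph$cell_id > 0),
            1660)
  expect_equal(peak_of(ph$label == 1 & phen_map == "control" & ph$cell_id > 0),
               1653, tolerance = 2.5)  # grid resolution 2.5 cm-1
})

test_that("chi3_domain Im band areas match the Gaussian truth within 5%", {
  bm <- band_model()
  ax <- seq(1400, 1900, 0.5)
  win <- ax >= 1540 & ax <= 1740
  for (p in c("control", "senescent")) {
    comp <- default_compositions(p)$nucleolus
    comp$ch <- 0
    model <- carsens:::lorentzian_chi3_from_composition(comp, chi_nr = 1)
    im <- analytic_im_chi3(model, ax)
    # per-line in-window areas: isolate each line analytically
    for (j in seq_len(nrow(model$lines))) {
      single <- lorentzian_chi3(0, model$lines[j, ])
      single$lines$amplitude <- model$lines$amplitude[j]
      a <- sum(analytic_im_chi3(single, ax)[win]) * 0.5
      expect_equal(a, model$lines$area[j], tolerance = 0.05)
    }
    total <- sum(im[win]) * 0.5
    g_tot <- comp$purine + comp$alpha + comp$beta
    expect_equal(total, g_tot, tolerance = 0.05)
  }
})

test_that("synthesis is bit-reproducible and mode-checked", {
  ph <- make_phantom(phantom_layout(n_control = 2, n_senescent = 1), seed = 2)
  nz <- noise_config(sd = 0.01, baseline_amplitude = 0.05)
  a <- synthesize_cube(ph, noise = nz, seed = 9)
  b <- synthesize_cube(ph, noise = nz, seed = 9)
  expect_identical(a$cube$values, b$cube$values)
  c <- synthesize_cube(ph, noise = nz, seed = 10)
  expect_false(identical(a$cube$values, c$cube$values))
  expect_error(synthesize_cube(ph, mode = "frequency_domain"), "mode")
  expect_error(noise_config(sd = -1), ">= 0")
})
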
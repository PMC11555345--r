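test_that("calibrate_axis recovers linear and quadratic maps", {
  cal <- calibrate_axis(c(100, 200), c(1000, 2000), order = 1)
  expect_equal(cal$coefficients, c(0, 10), tolerance = 1e-9)
  expect_equal(max(abs(cal$residuals)), 0, tolerance = 1e-9)
  expect_equal(predict(cal, 150), 1500)
  # quadratic through three constructed points
  px <- c(50, 150, 300)
  truth <- c(900, 3, -0.002)
  wn <- truth[1] + truth[2] * px + truth[3] * px^2
  cal2 <- calibrate_axis(px, wn, order = 2)
  expect_equal(cal2$coefficients, truth, tolerance = 1e-9)
  expect_error(calibrate_axis(c(100, 200), c(1000, 2000), order = 2),
               "order \\+ 1")
  expect_error(calibrate_axis(c(100, 200), c(2000, 1000), order = 1),
               "increasing")
  expect_error(calibrate_axis(c(100, 200), 1000, order = 1), "match")
})

test_that("outside-cell subtraction removes a shared background", {
  sc <- make_test_scene()
  cube <- sc$sim$cube
  b <- 0.3 + 0.001 * (cube$axis - 1500)
  shifted <- cube
  shifted$values <- sweep(cube$values, 3, -b, "-")  # add b everywhere
  outside <- sc$phantom$cell_id == 0
  corr <- subtract_outside_baseline(shifted, outside)
  expect_equal(corr$values, cube$values, tolerance = 1e-12)
  # zero outside pixels leave the cube unchanged
  same <- subtract_outside_baseline(cube, outside)
  expect_equal(same$values, cube$values, tolerance = 1e-12)
  expect_error(subtract_outside_baseline(cube, outside & FALSE), "empty")
})

test_that("outside-mean residual scales as 4 sigma over sqrt n", {
  set.seed(31)
  ny <- 40; nx <- 40; nv <- 64
  sigma <- 0.05
  b <- sin(seq(0, 3, length.out = nv))
  vals <- array(rep(b, each = ny * nx), c(ny, nx, nv)) +
    array(rnorm(ny * nx * nv, 0, sigma), c(ny, nx, nv))
  cube <- cars_cube(vals, seq_len(nv))
  outside <- matrix(FALSE, ny, nx); outside[1:10, ] <- TRUE
  n <- sum(outside)
  corr <- subtract_outside_baseline(cube, outside)
  flat <- matrix(corr$values, ny * nx, nv)
  resid_mean <- abs(colMeans(flat[as.vector(outside), ]))
  expect_gte(mean(resid_mean <= 4 * sigma / sqrt(n)), 0.99)
})

test_that("arPLS flattens baselines and preserves peaks", {
  x <- seq(1540, 1740, 1)
  # constant input: baseline equals it
  rc <- arpls(rep(5, length(x)), lam = 1e4)
  expect_lte(max(abs(rc$baseline - 5)), 1e-6 * 5)
  # slow quadratic only (lam matched to the 1 cm-1 grid)
  quad <- 2 + 0.01 * (x - 1540) - 2e-5 * (x - 1540)^2
  rq <- arpls(quad, lam = 1e4)
  expect_lte(max(abs(rq$corrected)), 0.01 * diff(range(quad)))
  # unit peak on the quadratic recovered within 5%
  rp <- arpls(quad + gaussian_band(x, 1, 1650, 22), lam = 1e4)
  expect_equal(max(rp$corrected), 1, tolerance = 0.05)
  # contracts: exact decomposition, bounded weights, baseline below max
  expect_equal(rp$baseline + rp$corrected,
               quad + gaussian_band(x, 1, 1650, 22), tolerance = 1e-12)
  expect_true(all(rp$weights > 0 & rp$weights <= 1))
  expect_lte(max(rp$baseline), max(quad + gaussian_band(x, 1, 1650, 22)))
  expect_lte(rp$iterations, 100)
  expect_error(arpls(c(1, NA, 3, 4, 5, 6, 7, 8)), "finite")
  expect_error(arpls(rep(1, 4)), ">= 8")
})

test_that("stage order does not matter when outside pixels are zero", {
  sc <- make_test_scene()
  outside <- sc$phantom$cell_id == 0
  a <- arpls_cube(subtract_outside_baseline(sc$sim$cube, outside))
  b <- arpls_cube(sc$sim$cube)
  expect_lte(max(abs(a$values - b$values)), 1e-6)
})

test_that("water-band removal separates water from amide components", {
  ax <- seq(1500, 1800, 1)
  sp_amide <- suppressWarnings(compose_region_spectrum(
    spectral_composition(0.4, 1, 0.5), ax))
  # off mode is the identity
  expect_identical(remove_water_band(sp_amide, mode = "off"), sp_amide)
  # pure water band: residual L2 <= 5%
  water <- tibble::tibble(wavenumber = ax,
                          intensity = gaussian_band(ax, 0.8, 1640, 90))
  rw <- remove_water_band(water)
  expect_lte(sqrt(sum(rw$intensity^2) / sum(water$intensity^2)), 0.05)
  # amide-only negative control: fitted water amplitude <= 1% of largest
  ra <- remove_water_band(sp_amide)
  amp_max <- max(amplitude_from_area(c(0.4, 1, 0.5), c(15, 30, 22)))
  expect_lte(attr(ra, "water_amplitude"), 0.01 * amp_max)
  expect_error(remove_water_band(sp_amide[ax > 1700, ]), "1640")
})

test_that("automatic outside mask finds the background", {
  sc <- make_test_scene()
  mask <- outside_mask_auto(sc$sim$intensity_2933)
  expect_true(all(mask[sc$phantom$cell_id == 0]))
  expect_false(any(mask[sc$phantom$label >= 2]))
})
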
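fake_fitmaps <- function(g1, g2, g0 = g1 * 0) {
  structure(list(g0 = g0, g1 = g1, g2 = g2, rss = g1 * 0,
                 converged = g1 == g1, pixel_size = 0.5,
                 mode = "fixed_shape", model = band_model()),
            class = "amide_fit_maps")
}

test_that("ratio_map computes and masks as specified", {
  g1 <- matrix(c(1, 1, 0.5, 1), 2, 2)
  g2 <- matrix(c(1, 0.8, 0.5, 0), 2, 2)
  r <- ratio_map(fake_fitmaps(g1, g2))
  expect_equal(r[1, 1], 0.5)          # g1 = g2 > 0
  expect_equal(r[2, 1], 0.8 / 1.8)    # 0.444...
  expect_equal(r[1, 2], 0.5)
  # g2 = 0 exactly: ratio 0 <= 1e-19, flagged invalid
  expect_true(is.na(r[2, 2]))
  expect_false(attr(r, "valid")[2, 2])
  # zero denominator also invalid
  r0 <- ratio_map(fake_fitmaps(matrix(0, 1, 1), matrix(0, 1, 1)))
  expect_true(is.na(r0[1, 1]))
  expect_error(ratio_map(fake_fitmaps(matrix(-1, 1, 1), matrix(1, 1, 1))),
               "negative")
})

test_that("subtraction_map scales by the perinuclear variance", {
  g1 <- matrix(0.5, 3, 3); g2 <- matrix(2, 3, 3)
  ring <- matrix(rep(c(TRUE, FALSE, TRUE), 3), 3, 3)
  s <- subtraction_map(fake_fitmaps(g1, g2), ring)
  expect_true(all(s == 1.5))          # +1.5, beta-rich side
  expect_equal(attr(s, "scale"), 1)   # zero variance: unit fallback
  expect_error(subtraction_map(fake_fitmaps(g1, g2), ring & FALSE),
               "non-empty")
})

test_that("indicators respect rescaling and threshold monotonicity", {
  set.seed(17)
  g1 <- matrix(runif(64, 0.2, 1), 8, 8)
  g2 <- matrix(runif(64, 0.2, 1), 8, 8)
  fm <- fake_fitmaps(g1, g2)
  fm_k <- fake_fitmaps(3.7 * g1, 3.7 * g2)
  r <- ratio_map(fm); rk <- ratio_map(fm_k)
  expect_equal(unclass(rk), unclass(r), tolerance = 1e-12)
  ring <- matrix(FALSE, 8, 8); ring[1, ] <- TRUE
  s <- subtraction_map(fm, ring); sk <- subtraction_map(fm_k, ring)
  expect_equal(unclass(sk)[1:64], 3.7 * unclass(s)[1:64], tolerance = 1e-12)
  # raising the mask threshold never unflags a pixel
  v1 <- attr(ratio_map(fm, mask_threshold = 0.3), "valid")
  v2 <- attr(ratio_map(fm, mask_threshold = 0.6), "valid")
  expect_true(all(v1 | !v2))
})

test_that("nucleolar means rise with the beta fraction in both maps", {
  ph <- make_phantom(phantom_layout(n_control = 1, n_senescent = 0), seed = 3)
  r_means <- c(); s_means <- c()
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    comps <- list(control = list(
      cytoplasm = composition_from_beta_fraction(1, 0.2, purine = 0.25),
      nucleoplasm = composition_from_beta_fraction(1.2, 0.25, purine = 0.45),
      nucleolus = composition_from_beta_fraction(1.6, f, purine = 0.6)))
    sim <- synthesize_cube(ph, compositions = comps, seed = 5)
    fm <- fit_cube(sim$cube)
    maps <- indicator_maps(fm, ph$label)
    nol <- ph$label == 3
    r_means <- c(r_means, mean(maps$ratio[nol & maps$valid]))
    s_means <- c(s_means, mean(maps$subtraction[nol]))
  }
  expect_true(all(diff(r_means) > 0))
  expect_true(all(diff(s_means) > 0))
})

test_that("senescent nucleoli outshine their nucleoplasm in subtraction", {
  sc <- make_test_scene()
  fm <- fit_cube(sc$sim$cube)
  maps <- indicator_maps(fm, sc$phantom$label)
  phen <- matrix(sc$phantom$cells$phenotype[pmax(sc$phantom$cell_id, 1)],
                 nrow(sc$phantom$label), ncol(sc$phantom$label))
  sen <- phen == "senescent" & sc$phantom$cell_id > 0
  expect_gt(mean(maps$subtraction[sc$phantom$label == 3 & sen]),
            mean(maps$subtraction[sc$phantom$label == 2 & sen]))
})
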
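test_that("segmentation recovers well-separated intensity levels exactly", {
  ph <- make_phantom(phantom_layout(n_control = 2, n_senescent = 2,
                                    dim = c(72, 72)), seed = 5)
  img <- matrix(0, 72, 72)
  img[ph$label == 1] <- 1; img[ph$label == 2] <- 2; img[ph$label == 3] <- 3
  seg <- segment_regions(img)
  expect_identical(seg$region, ph$label)
  # all-zero image: all background
  z <- segment_regions(matrix(0, 8, 8))
  expect_true(all(z$region == 0))
  expect_error(segment_regions(matrix(2, 8, 8)), "distinct")
  expect_error(segment_regions(matrix(-1, 8, 8)), "non-negative")
})

test_that("two nucleoli in one nucleus stay separate under 4-connectivity", {
  region <- matrix(0L, 16, 16)
  region[4:13, 4:13] <- 2L
  region[6:7, 6:7] <- 3L
  region[9:10, 9:10] <- 3L   # diagonal touch at (8,8)-(9,9) corners only
  lab <- label_components(region == 3)
  expect_equal(max(lab), 2)
  # diagonal-only contact does not merge components
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(label_components(m)), 2)
})

test_that("cell records pick the largest nucleolus and average over it", {
  region <- matrix(0L, 20, 20)
  region[2:19, 2:19] <- 1L
  region[4:17, 4:17] <- 2L
  region[5:9, 5:10] <- 3L     # 30 px nucleolus
  region[12:16, 5:14] <- 3L   # 50 px nucleolus
  ph <- structure(list(label = region,
                       cell_id = (region >= 1) * 1L,
                       cells = tibble::tibble(cell_id = 1L,
                                              phenotype = "control",
                                              cy = 10, cx = 10, radius = 9,
                                              nuclei = 1L),
                       pixel_size = 0.5),
                  class = "cars_phantom")
  g1 <- matrix(1, 20, 20); g2 <- matrix(1.5, 20, 20)  # ratio 0.6 everywhere
  fm <- structure(list(g0 = g1 * 0, g1 = g1, g2 = g2, rss = g1 * 0,
                       converged = g1 > 0, pixel_size = 0.5,
                       mode = "fixed_shape", model = band_model()),
                  class = "amide_fit_maps")
  maps <- indicator_maps(fm, region)
  rec <- extract_cell_records(ph, maps)
  expect_equal(rec$largest_nucleolus_size, 50L)
  expect_equal(rec$largest_nucleolus_mean_ratio, 0.6)
  expect_equal(rec$nuclei_count, 1L)
  # area arithmetic: pixel count times pixel_size^2 exactly
  expect_equal(rec$largest_nucleus_area, sum(region >= 2) * 0.25)
})

test_that("classification applies the strict 118 um2 mononuclear rule", {
  mk <- function(nuclei, area) tibble::tibble(nuclei_count = nuclei,
                                              largest_nucleus_area = area)
  expect_equal(classify_cell(mk(1, 117.9)), "control")
  expect_equal(classify_cell(mk(1, 118.0)), "large_nucleus")
  expect_equal(classify_cell(mk(2, 50)), "binucleate")
  expect_equal(classify_cell(mk(3, 300)), "binucleate")
  expect_error(classify_cell(mk(0, 10)), "no nucleus")
  # a 400 px nucleus at 0.5 um/px is 100 um2: still control-eligible
  expect_equal(classify_cell(mk(1, 400 * 0.25)), "control")
  # classification is a partition over any record with >= 1 nucleus
  set.seed(13)
  recs <- tibble::tibble(nuclei_count = sample(1:3, 50, replace = TRUE),
                         largest_nucleus_area = runif(50, 10, 250))
  cls <- classify_cells(recs)
  expect_true(all(cls$phenotype_class %in%
                    c("control", "binucleate", "large_nucleus")))
})

test_that("ground-truth masks reproduce the generator beta fractions", {
  sc <- make_test_scene()
  fm <- fit_cube(sc$sim$cube)
  maps <- indicator_maps(fm, sc$phantom$label)
  rec <- classify_cells(extract_cell_records(sc$phantom, maps))
  expect_true(all(rec$has_nucleus))
  truth <- sc$sim$truth$table
  for (i in seq_len(nrow(rec))) {
    want <- truth$beta_fraction[truth$phenotype == rec$phenotype[i] &
                                  truth$region == "nucleolus"]
    expect_equal(rec$largest_nucleolus_mean_ratio[i], want,
                 tolerance = 1e-6)
  }
  # phantom phenotypes map onto the classification rules
  expect_true(all(rec$phenotype_class[rec$phenotype == "control"] ==
                    "control"))
  expect_true(all(rec$phenotype_class[rec$phenotype == "senescent"] ==
                    "binucleate"))
})
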
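test_that("two-sample scheme matches the closed-form pooled t", {
  d <- data.frame(value = c(1:5, 3:7),
                  group = rep(c("a", "b"), each = 5))
  gc <- group_comparison(d, design = "ttest_scheme", control = "a")
  # closed form: means 3 and 5, s2 = 2.5 each, se = 1, |t| = 2, df = 8
  expect_equal(abs(gc$location$statistic), 2, tolerance = 1e-12)
  expect_equal(gc$location$p_value, 2 * pt(-2, df = 8), tolerance = 1e-12)
  expect_equal(gc$location$p_value, 0.08051624, tolerance = 1e-7)
  expect_false(gc$significant)
  td <- tidy(gc)
  expect_true(all(c("shapiro_wilk", "f_test", "student_t") %in% td$test))
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
})

test_that("identical groups are never significant", {
  d <- data.frame(value = rep(c(1, 2, 3, 4, 5), 2),
                  group = rep(c("a", "b"), each = 5))
  gc <- group_comparison(d, design = "ttest_scheme")
  expect_equal(gc$location$p_value, 1, tolerance = 1e-12)
  expect_false(gc$significant)
})

test_that("group_comparison validates its inputs", {
  d <- data.frame(value = c(1, 2, 1, 2, 3), group = c("a", "a", "b", "b", "b"))
  expect_error(group_comparison(d), "n >= 3")
  d3 <- data.frame(value = rnorm(9), group = rep(c("a", "b", "c"), each = 3))
  expect_error(group_comparison(d3, design = "ttest_scheme"), "two groups")
})

test_that("dunnett scheme compares every treatment to the control", {
  set.seed(19)
  d <- data.frame(value = c(rnorm(8, 0), rnorm(8, 2), rnorm(8, 0.2)),
                  group = rep(c("control", "dcb", "natural"), each = 8))
  gc <- group_comparison(d, design = "dunnett_scheme", control = "control")
  expect_equal(nrow(gc$location), 2)
  expect_true(any(grepl("dcb", gc$location$comparison)))
  expect_equal(gc$variance_test$method, "Bartlett test of homogeneity of variances")
  expect_true(gc$location$p_value[grepl("dcb", gc$location$comparison)] < 0.05)
  gl <- glance(gc)
  expect_equal(gl$n_total, 24L)
})

test_that("null permutations stay near the nominal error rate", {
  set.seed(23)
  vals <- rnorm(20)
  hits <- 0
  for (i in 1:1000) {
    g <- sample(rep(c("a", "b"), each = 10))
    p <- stats::t.test(vals[g == "a"], vals[g == "b"],
                       var.equal = TRUE)$p.value
    hits <- hits + (p < 0.05)
  }
  expect_lte(hits / 1000, 0.07)
})

test_that("synthetic control vs senescent nucleolar ratios separate", {
  set.seed(29)
  truth_c <- 0.30; truth_s <- 0.60; sd_cell <- 0.04
  d <- data.frame(
    value = c(rnorm(10, truth_c, sd_cell), rnorm(10, truth_s, sd_cell)),
    group = rep(c("control", "senescent"), each = 10))
  gc <- group_comparison(d, design = "ttest_scheme", control = "control")
  expect_true(gc$significant)
  expect_gt(gc$location$estimate, 0)
})

test_that("size-ratio regression matches the closed-form normal equations", {
  # collinear points: exact slope, R2 = 1
  rec <- tibble::tibble(largest_nucleolus_size = c(10, 20, 30, 40),
                        largest_nucleolus_mean_ratio = 0.1 + 0.004 * c(10, 20, 30, 40))
  r <- size_ratio_regression(rec)
  expect_equal(r$slope, 0.004, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  # five hand-listed points against the closed-form OLS solution
  x <- c(10, 20, 30, 40, 60); y <- c(0.30, 0.33, 0.34, 0.38, 0.42)
  rec5 <- tibble::tibble(largest_nucleolus_size = x,
                         largest_nucleolus_mean_ratio = y)
  r5 <- size_ratio_regression(rec5)
  expect_equal(r5$slope, 0.002405405, tolerance = 1e-6)
  expect_equal(r5$intercept, 0.277027, tolerance = 1e-6)
  expect_true(r5$r_squared >= 0 && r5$r_squared <= 1)
  td <- tidy(r5)
  expect_equal(td$estimate[td$term == "size"], r5$slope)
  expect_error(size_ratio_regression(
    tibble::tibble(largest_nucleolus_size = c(5, 5, 5),
                   largest_nucleolus_mean_ratio = c(0.1, 0.2, 0.3))),
    "variance")
  expect_error(size_ratio_regression(rec5[1:2, ]), ">= 3")
})
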
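axis_pr <- seq(1500, 1840, 1)

test_that("simulate_raw_cars matches the closed-form Lorentzian modulus", {
  # nonresonant only: constant intensity chiNR^2
  m0 <- lorentzian_chi3(chi_nr = 1.7)
  expect_true(all(simulate_raw_cars(m0, axis_pr)$intensity == 1.7^2))
  # single line, chiNR = 0: |A / (-i Gamma)|^2 = (A / Gamma)^2 at resonance
  m1 <- lorentzian_chi3(0, tibble::tibble(omega = 1650, area = pi * 1,
                                          gamma = 10))
  m1$lines$amplitude <- 1
  r1 <- simulate_raw_cars(m1, axis_pr)
  expect_equal(r1$intensity[r1$wavenumber == 1650], 0.01)
  # strong nonresonant background: dispersive dip above the line center
  m2 <- lorentzian_chi3(5, tibble::tibble(omega = 1650, area = 1, gamma = 10))
  r2 <- simulate_raw_cars(m2, axis_pr)
  expect_gt(r2$wavenumber[which.min(r2$intensity)], 1650)
  expect_error(simulate_raw_cars(
    lorentzian_chi3(1, tibble::tibble(omega = 2000, area = 1, gamma = 8)),
    axis_pr), "cover")
})

test_that("MEM retrieves a flat phase from a constant spectrum", {
  raw <- tibble::tibble(wavenumber = axis_pr,
                        intensity = rep(1, length(axis_pr)))
  ch <- mem_retrieve(raw)
  expect_lte(max(abs(ch$phase)), 1e-6)
})

test_that("MEM with error-phase correction recovers line positions", {
  m <- lorentzian_chi3(1, tibble::tibble(omega = 1650, area = pi * 8,
                                         gamma = 8))
  m$lines$amplitude <- 8
  raw <- simulate_raw_cars(m, axis_pr)
  ch <- correct_error_phase(mem_retrieve(raw))
  expect_lte(abs(axis_pr[which.max(ch$im)] - 1650), 2)
  # two-line input: both local maxima at the centers within 2 cm-1
  m2 <- lorentzian_chi3(1, tibble::tibble(omega = c(1650, 1667),
                                          area = c(6, 6) * pi,
                                          gamma = c(8, 8)))
  m2$lines$amplitude <- c(6, 6)
  ch2 <- correct_error_phase(mem_retrieve(simulate_raw_cars(m2, axis_pr)))
  im <- ch2$im
  locmax <- which(diff(sign(diff(im))) == -2) + 1
  peaks <- axis_pr[locmax][order(im[locmax], decreasing = TRUE)][1:2]
  expect_lte(min(abs(peaks - 1650)), 2)
  expect_lte(min(abs(peaks - 1667)), 2)
})

test_that("error-phase correction honors its contracts", {
  m <- lorentzian_chi3(1, tibble::tibble(omega = 1650, area = 2 * pi,
                                         gamma = 9))
  m$lines$amplitude <- 2
  ch_true <- carsens:::eval_chi3(m, axis_pr)
  mk <- function(phase) {
    out <- tibble::tibble(wavenumber = axis_pr, modulus = Mod(ch_true),
                          phase = phase, im = Mod(ch_true) * sin(phase))
    attr(out, "modulus_norm") <- Mod(ch_true)
    class(out) <- c("chi3_spectrum", class(out))
    out
  }
  # zero phase: unchanged
  z <- correct_error_phase(mk(rep(0, length(axis_pr))))
  expect_equal(z$phase, rep(0, length(axis_pr)), tolerance = 1e-12)
  # constant offset, order 0: removed exactly
  cst <- correct_error_phase(mk(rep(0.3, length(axis_pr))), order = 0)
  expect_equal(max(abs(cst$phase)), 0, tolerance = 1e-10)
  # true resonant phase plus a linear ramp: order-1 envelope recovers Im
  ramp <- 0.05 + 1e-3 * (axis_pr - min(axis_pr))
  cor <- correct_error_phase(mk(Arg(ch_true) + ramp), order = 1)
  rel_l2 <- sqrt(sum((cor$im - Im(ch_true))^2) / sum(Im(ch_true)^2))
  expect_lte(rel_l2, 0.05)
  expect_error(correct_error_phase(mk(rep(0, length(axis_pr))),
                                   order = length(axis_pr)), "order")
})

test_that("KK oracle behaves like MEM on simple inputs", {
  raw0 <- tibble::tibble(wavenumber = axis_pr,
                         intensity = rep(2, length(axis_pr)))
  expect_lte(max(abs(kk_oracle(raw0)$im)), 1e-6 * sqrt(2))
  m <- lorentzian_chi3(1, tibble::tibble(omega = 1650, area = 8 * pi,
                                         gamma = 8))
  m$lines$amplitude <- 8
  raw <- simulate_raw_cars(m, axis_pr)
  kk <- correct_error_phase(kk_oracle(raw))
  expect_lte(abs(axis_pr[which.max(kk$im)] - 1650), 2)
  # MEM vs KK band areas within 10% on a two-line input
  m2 <- lorentzian_chi3(1, tibble::tibble(omega = c(1650, 1667),
                                          area = c(5, 7) * pi,
                                          gamma = c(8, 8)))
  m2$lines$amplitude <- c(5, 7)
  raw2 <- simulate_raw_cars(m2, axis_pr)
  win <- axis_pr >= 1540 & axis_pr <= 1740
  a_mem <- sum(correct_error_phase(mem_retrieve(raw2))$im[win])
  a_kk <- sum(correct_error_phase(kk_oracle(raw2))$im[win])
  expect_equal(a_mem / a_kk, 1, tolerance = 0.1)
})

test_that("retrieval is scale-covariant and deterministic", {
  set.seed(21)
  m <- random_chi3_model(2)
  raw <- simulate_raw_cars(m, axis_pr)
  ch1 <- mem_retrieve(raw)
  raw_k <- raw
  raw_k$intensity <- raw$intensity * 7.3
  ch2 <- mem_retrieve(raw_k)
  expect_equal(ch2$phase, ch1$phase, tolerance = 1e-9)
  expect_equal(ch2$modulus, sqrt(7.3) * ch1$modulus, tolerance = 1e-9)
  expect_identical(mem_retrieve(raw)$im, ch1$im)
  expect_error(mem_retrieve(raw[1:32, ]), "64")
  bad <- raw; bad$intensity[5] <- -1
  expect_error(mem_retrieve(bad), "negative")
})

test_that("MEM matches the analytic oracle over random line systems", {
  # smaller replicate of the acceptance sweep, kept cheap
  set.seed(8)
  ax <- seq(1430, 1870, 1)
  win <- ax >= 1540 & ax <= 1740
  for (i in 1:5) {
    m <- random_chi3_model(sample(1:4, 1))
    raw <- simulate_raw_cars(m, ax)
    ch <- correct_error_phase(mem_retrieve(raw))
    expect_lte(abs(ax[which.max(ch$im)] - ax[which.max(raw$im_true)]), 2)
    for (j in seq_len(nrow(m$lines))) {
      bw <- ax >= m$lines$omega[j] - 3 * m$lines$gamma[j] &
        ax <= m$lines$omega[j] + 3 * m$lines$gamma[j]
      expect_equal(sum(ch$im[bw]) / sum(raw$im_true[bw]), 1,
                   tolerance = 0.1)
    }
  }
})
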
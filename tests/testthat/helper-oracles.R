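# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths wherever the quantity under test has a
# brute-force or closed-form alternative.

# dense-grid argmax of a composed spectrum (0.01 cm-1 resolution)
argmax_oracle <- function(composition, lo = 1540, hi = 1740) {
  nu <- seq(lo, hi, by = 0.01)
  sp <- suppressWarnings(compose_region_spectrum(composition, nu))
  nu[which.max(sp$intensity)]
}

# adaptive-quadrature area of an FWHM-parameterised Gaussian
gauss_area_oracle <- function(amplitude, fwhm) {
  stats::integrate(function(x) {
    amplitude * exp(-4 * log(2) * x^2 / fwhm^2)
  }, -10 * fwhm, 10 * fwhm, rel.tol = 1e-12)$value
}

# random Lorentzian chi3 model in the amide neighborhood
random_chi3_model <- function(n_lines, omega_range = c(1500, 1800),
                              area_range = c(0.5, 2),
                              gamma_range = c(6, 14),
                              chi_nr_range = c(0.5, 2)) {
  lines <- tibble::tibble(
    omega = stats::runif(n_lines, omega_range[1], omega_range[2]),
    area = stats::runif(n_lines, area_range[1], area_range[2]),
    gamma = stats::runif(n_lines, gamma_range[1], gamma_range[2]))
  m <- lorentzian_chi3(stats::runif(1, chi_nr_range[1], chi_nr_range[2]),
                       lines)
  m$lines$amplitude <- m$lines$area / pi
  m
}

# small phantom + noiseless cube shared by several tests
make_test_scene <- function(noise = noise_config(), seed = 11,
                            axis = seq(1500, 1800, by = 2.5),
                            n_control = 2, n_senescent = 2,
                            dim = c(72, 72)) {
  ph <- make_phantom(phantom_layout(dim = dim, n_control = n_control,
                                    n_senescent = n_senescent), seed = seed)
  sim <- synthesize_cube(ph, axis = axis, noise = noise, seed = seed + 1)
  list(phantom = ph, sim = sim)
}
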
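#' Lorentzian chi3 model
#'
#' Standard multiplex-CARS lineshape model: a real nonresonant constant
#' `chiNR` plus resonant Lorentzian lines,
#' `chi3(nu) = chiNR + sum_j A_j / (Omega_j - nu - i Gamma_j)`.
#' The raw CARS intensity is `|chi3|^2`; the Raman-equivalent spectrum
#' is `Im[chi3](nu) = sum_j A_j Gamma_j / ((Omega_j - nu)^2 + Gamma_j^2)`.
#'
#' @param chi_nr Nonresonant background (>= 0).
#' @param lines Tibble/data frame with columns `omega` (center, cm-1),
#'   `area` (integrated Im band intensity) and `gamma` (half width at
#'   half maximum of Im, cm-1, > 0). Amplitudes are derived from areas.
#' @return An object of class `lorentzian_chi3`.
#' @export
lorentzian_chi3 <- function(chi_nr = 1,
                            lines = tibble::tibble(omega = numeric(),
                                                   area = numeric(),
                                                   gamma = numeric())) {
  lines <- tibble::as_tibble(lines)
  if (chi_nr < 0) stop("lorentzian_chi3: chiNR must be >= 0")
  if (nrow(lines) && any(lines$gamma <= 0)) {
    stop("lorentzian_chi3: Gamma must be > 0")
  }
  structure(list(chi_nr = chi_nr, lines = lines), class = "lorentzian_chi3")
}

# amplitude so that the Im band area over `window` equals `area`
# (full-line area is A * pi; in-window matching avoids the fat
# Lorentzian tails when areas are compared against Gaussian truth)
lorentzian_amplitude <- function(area, omega, gamma, window = NULL) {
  if (is.null(window) || omega < window[1] || omega > window[2]) {
    return(area / pi)
  }
  span <- atan((window[2] - omega) / gamma) - atan((window[1] - omega) / gamma)
  area / span
}

# build a Lorentzian model matched to a composition's Gaussian truth:
# identical centers, Gamma = FWHM/2, amide areas matched in the fit window
lorentzian_chi3_from_composition <- function(composition, chi_nr = 1,
                                             model = band_model()) {
  comp <- composition_components(composition, model)
  comp <- comp[comp$area > 0, , drop = FALSE]
  w <- attr(model, "window")
  if (nrow(comp) == 0) return(lorentzian_chi3(chi_nr))
  lines <- tibble::tibble(
    omega = comp$center,
    area = comp$area,
    gamma = comp$fwhm / 2,
    amplitude = mapply(lorentzian_amplitude, comp$area, comp$center,
                       comp$fwhm / 2, MoreArgs = list(window = w)))
  out <- lorentzian_chi3(chi_nr, lines[c("omega", "area", "gamma")])
  out$lines$amplitude <- lines$amplitude
  out
}

# complex chi3 on an axis
eval_chi3 <- function(model, axis) {
  stopifnot(inherits(model, "lorentzian_chi3"))
  ch <- rep(complex(real = model$chi_nr), length(axis))
  if (nrow(model$lines)) {
    amp <- model$lines[["amplitude"]]
    if (is.null(amp)) amp <- model$lines$area / pi
    for (j in seq_len(nrow(model$lines))) {
      ch <- ch + amp[j] / complex(real = model$lines$omega[j] - axis,
                                  imaginary = -model$lines$gamma[j])
    }
  }
  ch
}

#' Analytic Im\[chi3\] of a Lorentzian model
#'
#' @param model A [lorentzian_chi3()].
#' @param axis Wavenumber axis (cm-1).
#' @return Numeric vector of exact Im values.
#' @export
analytic_im_chi3 <- function(model, axis) Im(eval_chi3(model, axis))

#' Simulate a raw multiplex CARS spectrum
#'
#' `intensity(nu) = |chiNR + sum_j A_j / (Omega_j - nu - i Gamma_j)|^2`.
#' The exact analytic Im\[chi3\] is stored alongside for oracle use.
#'
#' @param model A [lorentzian_chi3()].
#' @param axis Strictly increasing wavenumber axis; should cover every
#'   line to +/- 5 Gamma.
#' @return Tibble with columns `wavenumber`, `intensity`, `im_true`.
#' @export
simulate_raw_cars <- function(model, axis) {
  if (any(diff(axis) <= 0)) stop("simulate_raw_cars: axis must be strictly increasing")
  if (nrow(model$lines) &&
      any(model$lines$omega < min(axis) | model$lines$omega > max(axis))) {
    stop("simulate_raw_cars: axis must cover all line centers")
  }
  ch <- eval_chi3(model, axis)
  tibble::tibble(wavenumber = axis, intensity = Mod(ch)^2, im_true = Im(ch))
}

# smooth envelope normalization for tilted backgrounds: heavily
# penalized arPLS baseline of the intensity
raw_envelope <- function(intensity, lam = 1e7) {
  b <- arpls(intensity, lam = lam)$baseline
  pmax(b, max(intensity) * 1e-6)
}

# constant background estimate: median intensity. The retrieved phase
# is exactly invariant under constant rescaling of the spectrum, so a
# constant normalization adds no spurious phase; a shaped envelope
# does (its log-modulus acquires a Hilbert-transform phase of its own)
# and is only worth that cost when the nonresonant background is
# genuinely non-flat.
raw_constant_reference <- function(intensity) {
  rep(max(stats::median(intensity), max(intensity) * 1e-6),
      length(intensity))
}

#' Maximum-entropy-method phase retrieval
#'
#' Estimates the modulus and raw phase of chi3 from a raw CARS power
#' spectrum via the autoregressive (maximum entropy) spectral model.
#' The normalized intensity is treated as a power spectrum: its
#' autocorrelation coefficients are computed by discrete Fourier
#' transform, the Hermitian Toeplitz system is solved for the AR
#' coefficients, and the raw phase is the argument of the AR model.
#' Fully deterministic. The raw phase still contains a slowly varying
#' error phase; pass the result through [correct_error_phase()].
#'
#' @param raw Tibble with columns `wavenumber`, `intensity` (>= 0),
#'   e.g. from [simulate_raw_cars()]; the axis must be uniform.
#' @param pole_fraction Number of AR poles as a fraction of the number
#'   of samples (default 0.45; must give < N/2 poles).
#' @param normalization_reference Either a numeric reference spectrum
#'   to divide by, `"constant"` (default: divide by the median
#'   intensity - the retrieved phase is exactly invariant under
#'   constant rescaling, so a flat nonresonant background needs no
#'   shaped reference) or `"envelope"` (arPLS-smoothed envelope, for
#'   tilted backgrounds; a shaped reference contributes its own
#'   Hilbert phase and trades accuracy for flatness).
#' @param pad_fraction Fraction of N used for a cosine bridge appended
#'   to the spectrum before the autocorrelation, closing the periodic
#'   discontinuity that otherwise rings through the AR model.
#' @return An object of class `chi3_spectrum`: tibble with columns
#'   `wavenumber`, `modulus` (sqrt of raw intensity), `phase` (raw MEM
#'   phase, rad), `im` (modulus * sin(phase)); attributes `poles`,
#'   `corrected` (FALSE) and `modulus_norm`.
#' @export
mem_retrieve <- function(raw, pole_fraction = 0.45,
                         normalization_reference = "constant",
                         pad_fraction = 0.5) {
  axis <- raw$wavenumber
  S_raw <- raw$intensity
  N <- length(S_raw)
  if (N < 64) stop("mem_retrieve: need >= 64 samples")
  if (max(abs(diff(axis) - mean(diff(axis)))) > 1e-6 * mean(diff(axis))) {
    stop("mem_retrieve: axis must be uniform")
  }
  ref <- if (is.numeric(normalization_reference)) {
    normalization_reference
  } else if (identical(normalization_reference, "envelope")) {
    raw_envelope(S_raw)
  } else {
    raw_constant_reference(S_raw)
  }
  S <- S_raw / ref
  if (any(!is.finite(S)) || any(S < 0)) {
    stop("mem_retrieve: negative or non-finite intensities after normalization")
  }
  M <- floor(pole_fraction * N)
  if (M >= N / 2) stop("mem_retrieve: pole count must be < N/2")
  if (M < 2) stop("mem_retrieve: too few poles")
  # cosine bridge from S[N] back to S[1] removes the period jump
  P <- floor(pad_fraction * N)
  Sp <- if (P > 0) {
    t <- seq_len(P) / (P + 1)
    c(S, S[N] + (S[1] - S[N]) * (1 - cos(pi * t)) / 2)
  } else S
  Np <- length(Sp)
  v <- (seq_len(Np) - 1) / Np
  C <- vapply(0:M, function(m) mean(Sp * exp(1i * 2 * pi * m * v)),
              complex(1))
  dd <- outer(seq_len(M), seq_len(M), "-")
  Tm <- matrix(ifelse(dd >= 0, C[abs(dd) + 1], Conj(C[abs(dd) + 1])), M, M)
  a <- tryCatch(solve(Tm, -C[2:(M + 1)]),
                error = function(e) stop(
                  "mem_retrieve: Toeplitz system singular or ill-conditioned for pole count M = ",
                  M, call. = FALSE))
  ealpha <- exp(-1i * 2 * pi * outer(v[seq_len(N)], seq_len(M)))
  alpha <- 1 + as.vector(ealpha %*% a)
  phase <- Arg(alpha)
  out <- tibble::tibble(wavenumber = axis,
                        modulus = sqrt(pmax(S_raw, 0)),
                        phase = phase,
                        im = sqrt(pmax(S_raw, 0)) * sin(phase))
  attr(out, "poles") <- M
  attr(out, "corrected") <- FALSE
  attr(out, "modulus_norm") <- sqrt(pmax(S, 0))
  class(out) <- c("chi3_spectrum", class(out))
  out
}

#' Remove the slowly varying error phase
#'
#' The MEM (or Kramers-Kronig) raw phase contains the resonant phase
#' plus a slowly varying spurious component. Because the spontaneous
#' Raman spectrum is non-negative, the corrected (resonant) phase must
#' be >= 0 everywhere and touch zero off resonance - so the error
#' phase is the lower envelope of the raw phase. `"polynomial"`
#' (default) estimates it as a low-order polynomial fitted by
#' asymmetric iteratively reweighted least squares (points below the
#' current fit keep full weight, resonant excursions above it are
#' down-weighted); `"smooth"` subtracts a heavily smoothed (wide
#' running-mean) version of the phase, appropriate when the error
#' phase dominates the resonant one. The corrected Im is
#' `modulus * sin(corrected phase)`.
#'
#' @param chi3 A `chi3_spectrum` from [mem_retrieve()] or [kk_oracle()].
#' @param method `"polynomial"` or `"smooth"`.
#' @param order Polynomial order (default 0, i.e. a constant offset:
#'   with a flat nonresonant background the error phase left after
#'   padded, constant-normalized MEM is essentially constant, and
#'   every extra order absorbs a little more of the slowly varying
#'   Lorentzian wing pedestal. Raise it only for genuinely shaped
#'   backgrounds. Must be < number of samples.
#' @param asymmetry Weight given to points above the envelope fit
#'   (default 0.02; 1 would make the fit symmetric).
#' @param iterations Reweighting passes (default 10).
#' @return The input with `phase` replaced by the corrected phase, `im`
#'   recomputed, and attributes `corrected = TRUE`, `error_phase`.
#' @export
correct_error_phase <- function(chi3, method = c("polynomial", "smooth"),
                                order = 0, asymmetry = 0.02,
                                iterations = 10) {
  method <- match.arg(method)
  stopifnot(inherits(chi3, "chi3_spectrum"))
  phase <- chi3$phase
  if (any(!is.finite(phase))) stop("correct_error_phase: phase must be finite")
  N <- length(phase)
  axis <- chi3$wavenumber
  mod_n <- attr(chi3, "modulus_norm")
  if (is.null(mod_n)) mod_n <- rep(1, N)
  if (method == "smooth") {
    k <- max(5, 2 * floor(N / 8) + 1)
    err <- as.numeric(stats::filter(c(rep(phase[1], k), phase,
                                      rep(phase[N], k)),
                                    rep(1 / k, k), sides = 2)[(k + 1):(k + N)])
  } else {
    if (order >= N) {
      stop("correct_error_phase: polynomial order must be < number of samples")
    }
    u <- (axis - mean(axis)) / (diff(range(axis)) / 2)
    X <- if (order == 0) matrix(1, N, 1) else {
      cbind(1, stats::poly(u, degree = order, raw = TRUE, simple = TRUE))
    }
    w <- rep(1, N)
    err <- rep(0, N)
    for (it in seq_len(iterations)) {
      cf <- stats::lm.wfit(X, phase, w)$coefficients
      cf[is.na(cf)] <- 0
      err <- as.vector(X %*% cf)
      w_new <- ifelse(phase > err, asymmetry, 1)
      if (all(w_new == w)) break
      w <- w_new
    }
  }
  chi3$phase <- phase - err
  chi3$im <- chi3$modulus * sin(chi3$phase)
  attr(chi3, "corrected") <- TRUE
  attr(chi3, "error_phase") <- err
  attr(chi3, "modulus_norm") <- mod_n
  chi3
}

#' Kramers-Kronig phase-retrieval oracle
#'
#' Independent check on [mem_retrieve()]: the phase of a minimum-phase
#' response is the negative Hilbert transform of the log-modulus.
#' Computed on an edge-padded spectrum by FFT; intended for tests and
#' cross-validation, not as the production path.
#'
#' @inheritParams mem_retrieve
#' @return A `chi3_spectrum` (raw phase; apply [correct_error_phase()]).
#' @export
kk_oracle <- function(raw, normalization_reference = "constant") {
  axis <- raw$wavenumber
  S_raw <- raw$intensity
  N <- length(S_raw)
  if (N < 64) stop("kk_oracle: need >= 64 samples")
  ref <- if (is.numeric(normalization_reference)) {
    normalization_reference
  } else if (identical(normalization_reference, "envelope")) {
    raw_envelope(S_raw)
  } else {
    raw_constant_reference(S_raw)
  }
  S <- S_raw / ref
  if (any(!is.finite(S)) || any(S < 0)) {
    stop("kk_oracle: negative or non-finite intensities after normalization")
  }
  logm <- 0.5 * log(pmax(S, 1e-12))
  # edge-pad to 4N to soften circular-convolution artifacts
  pad <- c(rep(logm[1], N), logm, rep(logm[N], 2 * N))
  Np <- length(pad)
  f <- stats::fft(pad)
  h <- rep(0, Np)
  if (Np %% 2 == 0) {
    h[2:(Np / 2)] <- 1; h[(Np / 2 + 2):Np] <- -1
  } else {
    h[2:((Np + 1) / 2)] <- 1; h[((Np + 1) / 2 + 1):Np] <- -1
  }
  hilb <- Re(stats::fft(f * (-1i * h), inverse = TRUE)) / Np
  phase <- hilb[(N + 1):(2 * N)]
  out <- tibble::tibble(wavenumber = axis,
                        modulus = sqrt(pmax(S_raw, 0)),
                        phase = phase,
                        im = sqrt(pmax(S_raw, 0)) * sin(phase))
  attr(out, "poles") <- NA_integer_
  attr(out, "corrected") <- FALSE
  attr(out, "modulus_norm") <- sqrt(pmax(S, 0))
  class(out) <- c("chi3_spectrum", class(out))
  out
}
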
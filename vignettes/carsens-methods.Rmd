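---
title: "Methods: from raw CARS cubes to nucleolar senescence indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw CARS cubes to nucleolar senescence indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carsens)
```

## The measurement model

Multiplex CARS records, per pixel, an intensity spectrum
$I(\nu) = |\chi^{(3)}(\nu)|^2$ with
$\chi^{(3)}(\nu) = \chi_{NR} + \sum_j A_j/(\Omega_j - \nu - i\Gamma_j)$:
a real, nearly wavenumber-flat nonresonant background plus resonant
Lorentzian lines. The quantity of biological interest is
$\mathrm{Im}[\chi^{(3)}]$, which is proportional to the spontaneous
Raman spectrum. The pipeline estimates it per pixel, corrects
baselines, decomposes the amide I band and aggregates per cell.

## Maximum-entropy phase retrieval

`mem_retrieve()` treats the normalized intensity as the power spectrum
of an autoregressive (all-pole) model: autocorrelation coefficients are
computed by discrete Fourier transform, the Hermitian Toeplitz system
is solved for the AR coefficients, and the raw phase is the argument of
the AR transfer function. The default pole count is 0.45·N. The
procedure is deterministic; repeated calls are bit-identical.

Two implementation details matter in practice and are deliberate
choices of this package:

* **Normalization is constant by default.** The retrieved phase is
  exactly invariant under constant rescaling of the spectrum, so with a
  flat nonresonant background a constant (median-intensity) reference
  is the accuracy-optimal normalization. Dividing by a *shaped*
  self-estimated envelope instead contributes the envelope's own
  Hilbert-transform phase to the result; in our experiments that
  inflated phase error by roughly an order of magnitude and biased
  band areas by tens of percent. `normalization_reference = "envelope"`
  remains available for genuinely tilted instrument responses, and a
  measured reference spectrum can be passed directly.
* **The spectrum is bridge-padded.** The AR model is periodic in the
  reduced frequency; a cosine bridge from the last sample back to the
  first removes the wrap-around discontinuity that otherwise rings
  through the poles. This cut the residual phase error by about 10x.

### Error phase

The raw MEM phase is the resonant phase plus a slowly varying spurious
component. Because the spontaneous Raman spectrum is non-negative, the
corrected phase must be ≥ 0 and touch zero off resonance: the error
phase is therefore the *lower envelope* of the raw phase.
`correct_error_phase()` fits that envelope with a polynomial by
asymmetric iteratively reweighted least squares (points above the fit
are down-weighted by `asymmetry = 0.02`).

The default polynomial order is 0. With constant normalization and
bridge padding, the remaining error phase is essentially a constant
offset, and every additional polynomial order absorbs a little more of
the slowly varying Lorentzian *wing pedestal*, which is real signal:
in a sweep over random 1–4-line systems, order 0 kept all per-line band
areas within 10% of the analytic truth while order 4 biased them 30–60%
low. Raise the order only when a shaped background is expected (the
linear-ramp recovery test uses order 1).

The independent `kk_oracle()` (log-modulus Hilbert phase on an
edge-padded spectrum) cross-checks MEM in the tests. It rests on a
minimum-phase assumption and finite-window truncation, so it is held to
the dominant line of each system; on weak lines in dense four-line
systems it can drift by ~15–20% even when MEM matches the analytic
truth.

## Calibration and baselines

`calibrate_axis()` fits a first- or second-order polynomial from
detector pixel to wavenumber through reference peaks and refuses
non-monotone maps. Baseline correction is two-stage, in this order:

1. `subtract_outside_baseline()` subtracts the mean spectrum of all
   pixels outside the cells (mask supplied, or Otsu-thresholded from
   the 2933 cm⁻¹ CH image via `outside_mask_auto()`);
2. `arpls()` removes remaining slow per-pixel baseline variation with
   asymmetrically reweighted penalized least squares: a
   second-difference (Whittaker) penalty with logistic weights
   re-estimated each pass so peaks are excluded from the baseline.
   Defaults: `lam = 1e5`, `ratio_tol = 1e-6`, `max_iter = 100`. The
   stage runs per pixel (`arpls_cube()`, with a small C++ pentadiagonal
   solver; ~0.1 ms per spectrum) and can be switched off.

**Choosing `lam`.** The penalty acts on the *index* grid, so the
effective smoothing width in wavenumber scales as
`lam^(1/4) * spacing`. The default 1e5 is tuned to the pipeline's
2.5 cm⁻¹ sampling; on a 1 cm⁻¹ grid the equivalent choice is ~1e3–1e4
(`lam` scales as spacing⁻⁴). With `lam` matched to the grid, a pure
quadratic baseline is removed to ≲0.3% of its range and a unit peak of
FWHM 22 cm⁻¹ riding on it is recovered within 0.5%.

`remove_water_band()` (off by default; the generator omits water unless
asked) removes a broad 1640 cm⁻¹ band by joint non-negative fitting
with the amide components — fitting water alone would steal amide
intensity, the joint fit leaves amide-only spectra untouched.

## Amide I decomposition

`band_model()` fixes the three components (purine 1570/15, α-helix +
lipid 1650/30, β-sheet 1667/22 cm⁻¹; linewidths are FWHM — the
convention adopted here, configurable via the model object) and the
1540–1740 cm⁻¹ window. `fit_amide_band()` offers:

* `fixed_shape` (default): centers and widths held; amplitudes by
  non-negative least squares. This is a linear problem — exact on
  noiseless model spectra and robust per pixel. `fit_cube()`
  vectorizes it: one shared design matrix, one matrix product for the
  unconstrained solution, NNLS only for the rare pixels with a negative
  amplitude.
* `bounded_nonlinear`: Levenberg–Marquardt over centers and widths
  within boxes (±3 cm⁻¹ and ±20% by default), with amplitudes profiled
  out by NNLS inside the residual (variable projection), in two stages
  (centers first, then centers + widths). The joint 9-parameter fit
  has width-pinned local minima that the staged variable projection
  avoids; from centers started 5 cm⁻¹ off it recovers the generating
  centers to <0.01 cm⁻¹ and areas to machine precision.

The reported g values are analytic Gaussian areas
(`integrated_intensity()`), not peak amplitudes. Non-convergent pixels
are flagged and excluded downstream rather than zero-filled.

## Indicator maps and quantification

`ratio_map()` computes g₂/(g₁+g₂); pixels with ratio ≤ 10⁻¹⁹ or zero
denominator are invalid (rendered dark purple, excluded from all
statistics). `subtraction_map()` computes g₂−g₁ and derives its display
scale from the standard deviation in a perinuclear ring — interpreted
here as a 2-pixel morphological ring outside the nucleus mask
(configurable; the stored values are never rescaled). Rendered
subtraction maps clip at ±3 scale units, blue toward β-sheet.

`extract_cell_records()` scores each cell by the cross-sectional mean
of both indicators over the *largest nucleolus* (maximal pixel count;
ties broken by lowest component label, components 4-connected).
`classify_cell()` applies: control ⇔ one nucleus and area strictly
< 118 µm²; ≥2 nuclei ⇔ binucleate; else large-nucleus. Areas are pixel
count × pixel_size², with 0.5 µm/pixel the default sampling.

`group_comparison()` runs Shapiro–Wilk per group, then either Bartlett
+ Dunnett against the control (multivariate-t critical values via
multcomp) or F-test + pooled-variance two-tailed Student's t;
significance at p < 0.05. `size_ratio_regression()` is OLS of the
nucleolar mean ratio on nucleolus pixel count with the two-sided slope
p-value.

## The synthetic-data module

`make_phantom()` draws circular cells on a jittered, shuffled grid:
control cells one nucleus (radius 5 px ≈ 20 µm² at 0.5 µm/px),
senescent cells two disjoint nuclei and enlarged nucleoli. Geometry is
deliberately simple — downstream stages consume only intensities and
labels, so circles suffice.

`synthesize_cube()` composes each pixel's spectrum from its
(phenotype, region) composition as a weight-scaled sum of unit-area
bands; ground truth g values are exact by construction. The default
compositions were tuned once against a dense-grid argmax oracle so that
the summed amide band of the control cytoplasm peaks at 1653 cm⁻¹
(β-fraction 0.20), the control nucleolus at 1657 cm⁻¹ (β 0.30, below
the 1660 cm⁻¹ amyloid boundary) and the senescent nucleolus at
1665 cm⁻¹ (β 0.60, above it); region amplitudes and the CH-band
contrast (cytoplasm < nucleoplasm < nucleolus at 2933 cm⁻¹) are
arbitrary units chosen for realistic ordering, since absolute
concentrations are not part of the model. In `chi3_domain` mode the
cube is raw CARS intensity from Lorentzian lines with the same centers,
Γ = FWHM/2, and amplitudes matched so the *in-window* Im area equals
the Gaussian component area (full-line matching would leave ~7% of a
1667 cm⁻¹ line's area outside 1540–1740 in its tails). Noise is
additive Gaussian with an optional intensity-proportional (shot-like)
variance term and an optional smooth baseline field; the defaults
(sd 0.002, baseline 0.01 of signal scale) represent a well-exposed
measurement.

What the generator does *not* emulate: optical blur and the
point-spread function, polarization and NA effects, z-structure,
spectral instrument response, cosmic-ray spikes, and cell-to-cell
compositional heterogeneity beyond the per-cell jitter of
`mononuclear_sweep()`. Passing tests therefore demonstrate the
correctness of the *analysis chain* under its stated model, not
robustness to every artifact of real microscopy.

## Numerical choices and degenerate inputs

* Fit-window coverage below 20 samples, empty outside masks, n < 3
  groups, zero size variance, and cells without nuclei raise immediate
  errors; non-converged pixels and protein-free ratios propagate as
  masked values.
* A zero-variance scaling region falls back to a unit display scale.
* An all-zero segmentation input is all background; any other
  single-valued image is an error.
* Problem sizes in tests and the acceptance script (96×96×121 demo
  cubes, 64×64 single-cell sweeps, 20 random Lorentzian systems at
  1 cm⁻¹ over 1430–1870 cm⁻¹) were chosen so the full pipeline runs in
  seconds on one core while leaving every stage's behavior measurable.

## Known limitations

* MEM accuracy is quoted for flat nonresonant backgrounds; strongly
  shaped backgrounds need a measured reference and a higher error-phase
  order, trading wing fidelity.
* The 118 µm² nucleus-area rule and the three-component band model are
  taken as fixed biology-derived constants; other cell types may need
  different thresholds or components.
* Dunnett p-values use the multivariate-t distribution and are exact
  only under normality and homoscedasticity — which the scheme's
  pre-tests are there to check.
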
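---
title: "Simulated dual-energy CESM: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated dual-energy CESM: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cesmsim)
```

## The problem

Contrast-enhanced spectral mammography acquires two registered radiographs of
an iodine-enhanced breast, one below and one above the iodine K edge at
33.17 keV, and recombines them so that only the contrast agent remains
visible. `cesmsim` is a desk-scale sandbox for that processing chain: it
synthesizes the raw dual-energy pairs from a digital phantom under a
controlled noise model, so that the two recombination strategies — K-edge
subtraction (KES) and two-material basis decomposition — and their
dose/image-quality trade-offs can be studied quantitatively, with known
ground truth, at any dose.

## Forward model and its assumptions

A radiograph is simulated as

$$N(x,y) = t \, \phi_{px} \sum_E w(E)\, \exp\Big(-\sum_m \mu_m(E)\, t_m(x,y)\Big),$$

with exposure time $t$ (s), per-pixel fluence rate $\phi_{px}$ (photon rate /
beam area × pixel area), spectral weights $w(E)$ and per-material thickness
maps $t_m$ (cm). The assumptions, all deliberate simplifications:

- **Parallel beam.** The source–detector distance (16 m) exceeds the phantom
  thickness by three orders of magnitude, so cone-beam magnification is
  ignored.
- **Ideal photon-counting detector.** An optional scalar efficiency is the
  only detector response; scintillator blur, glare and electronic noise are
  omitted. Noise is purely Poisson, sampled per pixel with an explicit seed
  that is recorded in the output metadata.
- **No scatter or beam hardening.** With a few-percent-bandwidth beam the
  monochromatic treatment is accurate to the sub-percent level; a regression
  test checks that the quasi-monochromatic log-attenuation stays within 0.5%
  of the monochromatic value at the central energy.
- **Quasi-monochromatic spectra as truncated Gaussians.** Only the central
  energy and FWHM of the source are constrained (0.89 keV at 25 keV, 1.50 keV
  at 35 keV); the shape is otherwise unspecified, so a Gaussian truncated at
  ±3σ and renormalized is used. A delta spectrum (`fwhm = 0`) reduces the
  projector to exact Beer–Lambert transport, which the tests exploit.

Images are corrected as `(raw − dark)/(flat − dark)` with the flat acquired
through 6 cm of PMMA, the protocol for low-contrast breast imaging; the
log-attenuation `A = −ln(corrected)` is therefore referenced to that PMMA
block. Non-positive pixels (possible only under extreme noise) are masked
with an explicit mask and a warning rather than propagated as NaN.

## The synthetic phantom

`build_phantom()` renders a digital stand-in for a mammographic accreditation
phantom with an added contrast insert:

- a uniform 4.2 cm slab of 50/50 glandular/adipose tissue (the equivalent
  compressed-breast thickness is not standardized for this phantom, so it is
  a configurable default);
- calcium speck groups (microcalcifications) as uniform-thickness discs,
  default diameter 0.32 mm from a configurable 0.16–0.54 mm ladder, placed on
  a ring with seed-controlled jitter;
- tumour masses as spherical-cap (lens) excess thickness of the slab
  material, default diameter 2 mm from a 0.25–2.0 mm ladder;
- fibres as thin rotated rectangles of excess slab-material thickness,
  default 1 cm × 0.75 mm at 45°;
- a 1 cm × 3 cm rectangle of 6 mg/ml iodine solution with 1 cm internal path:
  the iodine map gets `concentration / ρ_iodine` cm of elemental-iodine
  equivalent per cm of solution (1.217 × 10⁻³ cm at the default
  ρ = 4.93 g/cm³) and the water map the remainder of the path.

Masses and fibres add to the breast-tissue map rather than introducing
separate materials: their attenuation is near-tissue, which is exactly why
both vanish in a correct iodine image, and modelling them as excess
glandular-equivalent thickness reproduces that behaviour without inventing
attenuation tables the method never uses.

Speck and tube footprints are rasterized with exact pixel coverage (analytic
disc–pixel and rectangle–pixel intersection areas); masses and fibres are
supersampled. Total material volume is therefore conserved under grid
refinement, which a property test checks at 1% between 142 μm and 71 μm
pitches. Real mammograms differ from this phantom in ways that matter for
absolute claims: anatomical texture (power-law background clutter), scatter,
detector MTF and electronic noise are all absent, so passing tests validate
the *processing arithmetic and noise bookkeeping*, not clinical detectability.

## Attenuation data and the decomposition basis

Linear attenuation tables for iodine, calcium, 50/50 breast tissue, PMMA and
water (15–40 keV) ship as CSV fixtures with representative magnitudes from
standard photon cross-section compilations; log-log interpolation is used
between grid points because attenuation is near power-law between edges. The
iodine K edge is carried as two grid points 4 eV apart so interpolation never
bridges the discontinuity. The 25/35 keV iodine and calcium entries are
anchored bit-exactly to the decomposition-basis coefficients
(68.796/154.109 and 10.650/4.097 cm⁻¹), which are interpreted as *elemental*
linear attenuation values — hence `d_I` and `d_C` are pure-element-equivalent
thicknesses in cm, the standard basis-image unit.

## The two recombinations

**KES.** `A_high − (E_low/E_high)³ A_low`. The cube factor is applied to the
*low*-energy log-attenuation: with μ ∝ 1/E³, `A_high = (E_low/E_high)³ A_low`
for any purely photoelectric material, so this is the only direction in which
the correction nulls such a background identically (a test requires
cancellation below 10⁻¹²). The Compton component of real tissue leaves a
uniform residual which is deliberately not flattened away.

**Two-material decomposition.** The per-pixel 2 × 2 system is solved in
closed form; the basis determinant (−1359.40 cm⁻²) is validated at
construction. Compose-then-decompose is the identity to better than 10⁻⁹ on
noiseless monochromatic input, and the solve is linear, so negative
thicknesses occur under noise and are *kept* by default — clipping would bias
every downstream noise statistic; a `clip` flag exists for display only.

### Why KES edges out the decomposition in this model

Both recombinations are fixed linear combinations of the same two
log-attenuation maps, so their iodine-image CNR ratio is fully determined by
the weights and the per-image noise. Rescaled to equal iodine signal, the
calcium-nulling decomposition has per-pixel variance
$0.151\,\sigma_l^2 + 1.022\,\sigma_h^2$ versus KES's
$0.133\,\sigma_l^2 + \sigma_h^2$ — strictly larger for every noise split. The
exact-calcium-cancellation constraint costs a few percent of CNR relative to
the cube-law correction under Poisson-only noise, and the simulated
decomposition iodine CNR accordingly lands a few percent *below* the KES CNR
at matched pair dose (the acceptance suite measures the ratio at about 0.94).
Measured data can rank the methods the other way through effects outside
this model (detector spectral response, scatter, the real phantom's deviation
from the two-material idealization); the simulation makes the variance
trade-off itself visible, which is the point of a desk-scale sandbox.

## Dosimetry

Air kerma per energy bin is `K(E) = E · Φ(E) · (μen/ρ)_air(E)` with the unit
chain made explicit (1 mGy = 6.2415 × 10⁹ keV/g), and
`MGD = Σ K(E) · 0.114 · DgN(E)` with DgN interpolated linearly. The 0.114
R/mGy exposure conversion lives in exactly one place
(`roentgen_per_mgy()`). The shipped DgN table is a clearly-labelled synthetic
stand-in for a 4.2 cm, 50% glandularity breast: no test depends on DgN
magnitudes, only on the formula's arithmetic, and quantitative work should
supply a literature table. Pair dose is bookkept as the sum of the two
acquisitions' MGDs, and the per-pair low/high exposure split is configurable
(`high_low_exposure_ratio`) because real protocols split unequally.

## Image-quality metrics

**CNR** is `(mean(signal) − mean(reference)) / sd(noise)` over a three-box
ROI set; it is affine-invariant and undefined (an error) on constant images.
The **CNR uncertainty** splits each ROI into `n_splits` blocks along its
longer axis and reports `sd(block CNRs)/√n_splits`. Because each block holds
`1/n_splits` of the area, block CNRs scatter √n_splits more than the full-ROI
CNR; dividing by √n_splits makes the estimate target the full-ROI standard
error and renders it approximately independent of `n_splits` (a simulation
test checks it against replicate scatter). Any estimator whose output shrank
like 1/√n_splits at fixed total area would not be estimating a fixed
population quantity.

**Resolution** follows a power-spectrum recipe: `|FFT|²` of the mean-removed
image, smoothed with a Gaussian of σ = 0.9 frequency-grid pixels (the
"kernel of 0.9" is ambiguous in prose, so σ is an exposed parameter),
radially averaged to Nyquist, with the noise baseline taken as the *median*
radial power over the top decile of frequencies (median for robustness to
residual signal — the estimator itself is a design choice, as is the radial
binning). The reported resolution is the highest radial frequency whose
power still reaches twice the baseline, converted to lp/mm via the pixel
pitch and capped at Nyquist (7.04 lp/mm at 71 μm). On blurred-plus-white-noise
test images this decreases monotonically with blur and scales exactly with
pitch; on a flat spectrum it returns the lowest bin with a warning. Because
the simulated detector has no MTF, simulated resolutions reflect the
noise/signal crossing, not optical blur.

## Statistics

Spearman's r is the Pearson correlation of mean ranks; its significance uses
`t = r√(n−2)/√(1−r²)` against the two-sided Student critical value. The
Kruskal–Wallis H implements the raw rank-sum formula without tie correction —
matching the printed form of the statistic, with the standard correction
available behind `tie_correct = TRUE` — and is tested against an independent
counting-rank implementation and for its null level (rejection rate 0.05 ±
0.02 at the χ²(2) critical value over 2000 simulations). Dose–CNR series are
fitted as `CNR = a√MGD` *through the origin*: the Poisson propagation
`σ(−ln I/I₀) = 1/√I` forces proportionality, so an intercept would absorb
noise (an intercept variant exists as a diagnostic). `dose_at_cnr()` inverts
the fit; matched-CNR dose ratios between methods are `(a₂/a₁)²` independent
of the target CNR.

## Numerical and reproducibility choices

- Every stochastic stage draws from a seed derived deterministically from
  the experiment's base seed; the caller's RNG stream is never disturbed.
- Noiseless projections are bit-exact repeatable; end-to-end runs are
  bit-identical for identical configs and seeds.
- TIFF export rescales each page to the unit range and records the
  offset/scale pair in the JSON sidecar (the R `tiff` writer stores integer
  sample formats), so counts, log-attenuation and thickness maps round-trip
  to 32-bit precision.
- Test problem sizes: the unit suite uses reduced fields of view
  (roughly 160 × 240 px with a 0.5 cm × 0.8 cm tube) and 11-bin spectra;
  the acceptance checks use the full 480 × 640 px default phantom with
  51-bin spectra, 100 × 100-pixel ensembles for the noise law, and
  2000 simulations for the Kruskal–Wallis null level. These sizes were chosen
  so the whole suite runs on a laptop in well under a minute per file while
  keeping Monte-Carlo error far inside each assertion's tolerance.

## Known limitations

No scatter, detector MTF/DQE, electronic noise, anatomical clutter or
three-material decomposition; dosimetry is per-bin arithmetic, not Monte
Carlo, and the shipped DgN values are synthetic; the clinical recombination
of commercial CESM devices is proprietary and out of scope. Conclusions
about *absolute* clinical image quality should not be drawn from this
sandbox — its purpose is exact, reproducible arithmetic around the
recombination methods themselves.
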
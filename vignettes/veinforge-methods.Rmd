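---
title: "Despeckling and segmenting retinal vessels with veinforge"
author: "veinforge maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Despeckling and segmenting retinal vessels with veinforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fundus photographs are corrupted by multiplicative (speckle) noise from the
coherent scattering of the illumination, on top of weaker additive sensor
noise. Speckle hides the thinnest retinal vessels from unsupervised
detectors, and those vessels carry much of the diagnostic signal for
diabetic retinopathy and related disease. veinforge implements a
despeckling-first segmentation strategy: restore the image with a filter
whose noise model actually matches speckle, then run a standard vesselness
detector and an automatic global threshold on the restored image.

## The speckle model

A noisy amplitude is `z(k) = x(k) u(k)`, where `x` is the clean intensity
and `u` an independent multiplier with `u0^2 ~ Gamma(shape = L,
scale = 1/L)` — the L-look square-root-Gamma (Nakagami) amplitude model.
We rescale `u = u0 / E[u0]` with `E[u0] = Gamma(L + 1/2)/(Gamma(L)
sqrt(L))` so the multiplier has unit mean and the expected noisy image
equals the clean one; `speckleMultiplierVar(L)` is then the per-pixel
relative noise power, decreasing in the number of looks `L`. The phantom
generator (`applySpeckle`) and the denoiser's noise calibration use the
same two functions, so the calibration invariant is testable in closed
form.

## S-BM3D: collaborative filtering under speckle

`sbm3dDenoise` follows the two-pass block-matching 3D architecture,
adapted to speckle at each step:

* **Grouping.** For each reference patch (stride `step`), every candidate
  patch in the `searchWindow` is scored by the probabilistic amplitude
  distance `D = sum (2L-1) log(a_s/a_t + a_t/a_s) + gamma
  (xhat_s - xhat_t)^2 / (xhat_s xhat_t)`; the `maxGroup` closest patches
  form the 3-D group. The first pass uses only the likelihood term
  (`gamma = 0`) because no prior image exists yet; the second pass adds the
  prior term computed on the pass-1 estimate (default `gamma = 4`; the
  weight has no published value and is exposed as configuration).
  Amplitudes are clamped at `1e-6` because the log-ratio is undefined at
  zero. The reference's self-distance is computed through the same
  floating-point accumulation as every candidate so that tying candidates
  can never displace the reference from its own group by a rounding ulp —
  on locally constant regions this matters, and it is what guarantees the
  aggregation covers every pixel.
* **Transform.** Each patch is decomposed with an undecimated separable
  Daubechies 8-tap wavelet (2 levels, circular extension) built as a tight
  frame (analysis and synthesis filters scaled by `1/sqrt(2)`), so
  reconstruction is exact for any block size and the white-noise variance
  gain of every subband is computed exactly from impulse responses. An
  orthonormal Haar transform runs along the stacking axis (hence
  `maxGroup` a power of two).
* **Pass 1 — LLMMSE.** Every coefficient is shrunk toward its
  subband-slice mean by `sx2/(sx2 + sn2)` with `sx2 = max(0, total - sn2)`;
  `sn2` is the subband gain times `speckleMultiplierVar(L)` times the
  squared mean amplitude of the group (the local linearization of the
  multiplicative model). Hard thresholding, appropriate for Gaussian
  noise, is deliberately not used.
* **Pass 2 — empirical Wiener.** Groups are re-formed with the full
  distance; noisy coefficients are scaled by `Xp^2/(Xp^2 + V2)` where `Xp`
  are the pass-1 prior coefficients and `V2` is the mean squared
  prior-noisy difference over the coefficient's subband slice. We chose
  the subband slice as the averaging support for `V2`: it is the same
  locality the LLMMSE statistics use, and the limiting behaviors (identity
  when prior equals noisy, zero when the prior vanishes) are preserved.
* **Aggregation.** Every pixel's estimates are combined by the weighted
  mean `sum(w x)/sum(w)` with `w = 1/(1 + residual variance)` per group.
  The normalized form (dividing by the weight sum rather than the group
  count) is the convention that preserves constants for any weights, which
  the constant-image fixed-point tests pin down.
* **Borders.** The image is padded symmetrically by half the search window
  so border pixels receive full search windows; the pad is cropped after
  aggregation.

The filter has no random state: two runs are bit-identical.

## The ensemble

A single S-BM3D run leaves periodic checkerboard artifacts locked to its
block geometry. `ensembleDenoise` runs the filter for a grid of
parameterizations — by default block size in {4, 8} crossed with search
window in {24, 39} — and averages the outputs with uniform weights. The
members' artifact patterns differ in period and phase and average out,
while the vessel structure they share survives. `checkerboardEnergy`
quantifies the artifacts as the fraction of AC spectral power in narrow
bands around `1/period` and `2/period` along either image axis (period
defaulting to the largest member block size); the acceptance suite checks
that the ensemble's energy does not exceed the median member's, and that
ensembling does not blur (its MAE against the clean phantom stays within
5% of the best member's).

## Detectors

Both detectors assume bright ridges; the preprocessing inverts the green
channel for real (dark-vessel) fundus images.

**Eigenvalue-ratio (improved Frangi) filter.** At each scale `s` the
gamma-normalized Hessian (`s^2` times Gaussian second derivatives) is
diagonalized; with `lambda2` the larger-magnitude eigenvalue sign-flipped
to be positive on bright ridges, the regularized `lambda_rho` equals
`lambda2` above the cutoff `tau * max(lambda2)` (per scale, over the FOV)
and `tau * max(lambda2)` below it, and the response is 0 for non-ridge
signs, 1 on the plateau `lambda2 >= lambda_rho/2`, and
`lambda2^2 (lambda_rho - lambda2) [3/(lambda2 + lambda_rho)]^3` in
between, maximized over scales. Because the response depends on an
eigenvalue *ratio*, faint thin vessels score as high as thick ones — and,
by the same token, the `tau` cutoff is the only thing separating vessels
from noise curvature, which is why this detector is the more sensitive of
the two to residual noise. Default `tau = 0.5` (midrange; no published
value). Default scales are 2, 3, 4.5 and 6 px: the response of a Gaussian
ridge of cross-section `sigma` extends to roughly `sqrt(sigma^2 + s^2)`,
so covering vessel half-widths up to two sigma (the ground-truth
definition, about 2-6.5 px across the phantom's vessel classes) requires
scales up to about `sigma * sqrt(3)`. An earlier draft used scales 1-3 px;
on the phantom those leave the outer half of every medium and thick vessel
with zero response (a quarter of all true vessel pixels), which is a
geometry error rather than a tuning preference, so the default was
corrected.

The classic two-factor Frangi filter (`classicFrangi`) is also provided,
in the two-factor form `(1 - exp(-R_A^2/2 alpha^2)) (1 - exp(-S^2 /
2 kappa^2))` with `R_A = |lambda1|/|lambda2|` and
`S = sqrt(lambda1^2 + lambda2^2)`. Note this form rewards blob-like
eigenvalue ratios rather than penalizing them and depends on eigenvalue
magnitudes — exactly the weaknesses the ratio-based filter was introduced
to remove; it is retained for comparison, not used by the pipeline.

**Multiscale line detector.** Oriented anisotropic Gaussian
second-derivative kernels `g_uu` with elongation `sigmaU = ratio *
sigmaV`, widths `sigmaV` in {4, 5}, ratios 0.5-3.5 in steps of 0.5 and
12 orientations every 15 degrees (168 kernels); the response is the
per-pixel maximum of `sigmaU^alpha * sigmaV^beta` times the negated
convolution, with `alpha = 1`, `beta = 0.5` (the exponents favoring thin
low-contrast vessels). `theta` orients the kernel's ridge axis along
`(sin theta, cos theta)` in (column, row) coordinates; kernels are sampled
on `±4 max(sigmaU, sigmaV)` supports (capped at the image half-side) and
mean-subtracted to an exactly zero sum. Orientation sampling at 15
degrees resolves the thinnest phantom bars; the grid is closed under
quarter turns, which the rotation-consistency tests exploit.

## The pipeline

`segmentVessels` chains: green-channel extraction (inverted for dark
vessels) → FOV handling → CLAHE → ensemble S-BM3D → Perona-Malik
anisotropic diffusion → detector → ISODATA threshold → binary mask.
Decisions worth recording:

* **FOV rim.** Pixels outside the field of view are set to the FOV mean
  before any filtering. The dark rim otherwise imprints an enormous
  artificial edge whose Hessian response dwarfs every vessel and corrupts
  the per-scale normalization of the ratio filter.
* **CLAHE** (8x8 tiles, clip limit 2.0 on 256 bins — the canonical
  defaults) computes tile histograms over FOV pixels only, so the border
  cannot dominate rim tiles. Degenerate tiles (a single occupied bin)
  keep the identity mapping, making constant images fixed points. Channel
  inversion precedes CLAHE, fixing an order the source pipeline leaves
  unstated.
* **Noise calibration.** CLAHE changes the noise level (with a clip limit
  of 2 it can roughly double local contrast, noise included), so a fixed
  `L` cannot describe the denoiser's actual input. The pipeline therefore
  estimates the effective number of looks from the enhanced image itself:
  the noise standard deviation from the MAD of neighbor differences
  (robust to the sparse vessel edges), divided by the mean FOV intensity
  and inverted through `speckleMultiplierVar`. This keeps the pipeline
  free of an a-priori noise parameter — the design goal of a fully
  data-driven filter — and a clean input simply maps to a very large `L`,
  making the filter approach the identity. Set `autoLooks = FALSE` to
  supply `L` manually.
* **Diffusion placement.** Perona-Malik diffusion (30 iterations,
  `kappa = 0.1`, `dt = 0.2`, exponential conduction, reflective borders)
  is applied to the *denoised image* before detection. Its role is to
  level sub-`kappa` residual fluctuations while the vessel edges (contrast
  well above `kappa`) survive; applied there it protects the
  ratio-based detector from saturating on noise curvature. Applying it
  after the detector instead (the `diffusionStage = "post"` switch)
  smooths the response map but leaves the detector exposed to the
  residual noise, which measurably degrades both detectors on the
  phantom, so the pre-detector placement is the default. The source
  description is ambiguous about this ordering; both placements are
  implemented.
* **ISODATA threshold.** 256 bins over the occupied range of the masked
  vesselness values, initialized at the Otsu level, iterating
  `T <- (mu0 + mu1)/2` to convergence (change below half a bin width, at
  most 100 iterations). Ties at `T` go to the vessel class. The printed
  form of the update ("mu0 + mu1 / 2") is read as the class-mean midpoint
  of the Ridler-Calvard iteration it cites. The suggestion of
  initializing from a background-only region conflicts with the Otsu
  initialization stated alongside it; Otsu is used.
* No components are removed and no holes filled by default
  (`minComponent = 0`); the flag exists for users who want it.

## The phantom generator

`generatePhantom` renders vessels as Gaussian-profile ridges
(`background + A exp(-d^2/2 sigma^2)` at perpendicular distance `d`;
overlaps take the maximum, so centerline values are exact) inside a
centered circular FOV, with straight or quadratic-Bezier centerlines.
Ground truth is the set of pixels within `2 sigma` of a centerline
(~95% of the profile mass) intersected with the FOV; dark phantoms are the
inverted rendering, mirroring real fundus polarity. The default layout
(256 px) has two thick arcades (`sigma` 3.2 px, contrast 0.40), three
medium branches (2.0 px, 0.32) and four thin vessels (1.1 px, 0.25) —
widths and thick-to-thin contrast grading chosen to span the vessel
calibres a fundus pipeline must handle, fixed once as the study
conditions. `randomVesselTree` grows randomized branching layouts for
property-style tests. What the phantom deliberately omits: optic disc,
macula, exudates, illumination gradients, and any background texture.
Passing on phantoms therefore demonstrates the machinery (noise model,
artifact suppression, geometry recovery), not clinical performance; the
evaluation harness accepts user-supplied public datasets (DRIVE, STARE,
CHASE_DB1) for that purpose but none are bundled or downloaded.

The additive noise magnitude is never specified in the source material;
`additiveSigma` defaults to 0 and is exposed.

## Numerical choices and degenerate inputs

Transforms reconstruct to 1e-8 or better; Hessian kernels are
moment-corrected (zero sum, exact second moment) so polynomial images
differentiate exactly; the 2x2 eigen-decomposition is closed-form.
Constant images are fixed points of CLAHE, the denoiser, the ensemble and
diffusion, and map to zero vesselness; a constant masked region makes
`isodataThreshold` fail loudly rather than return an arbitrary level.
Problem sizes in the tests — a 256 px phantom for the study conditions,
96-128 px for property checks, 1e5-1e6 draws for the speckle moments —
were chosen as the smallest sizes at which the quantities stabilize well
inside the asserted tolerances.

## Known limitations

* The amplitude-domain processing assumes the multiplicative model;
  after nonlinear contrast enhancement it holds only approximately (the
  data-driven `L` absorbs the scale change but not the shape change).
* ISODATA is a global threshold: on maps whose vessel responses span a
  wide range it is conservative, trading sensitivity for specificity.
* The flat phantom background is *harder* on the ratio-based detector
  than real tissue in one respect: any residual texture is pure noise
  curvature, with no true structure to dominate it.
* Color handling is minimal (green channel only); no illumination-field
  correction is attempted.
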
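---
title: "FFT-based myocyte orientation and disarray mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FFT-based myocyte orientation and disarray mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(myodisarray)
```

This vignette is the package's account of its model, its tunable parameters,
the numerical choices made where the design was genuinely open, and what the
synthetic experiments do and do not demonstrate about real data.

## The measurement model

α-actinin staining highlights sarcomere Z-bands: planes of protein spaced
T ≈ 1.6–2.0 µm apart, perpendicular to the cardiomyocyte long axis. A small
tissue block therefore behaves like a noisy 3D grating, and its power
spectrum concentrates energy in two symmetric peaks at radius 1/T along the
cell axis. Orientation estimation reduces to peak localization in the 3D
spectrum.

Axes follow the acquisition convention: arrays are indexed (Z, Y, X) with Y
the longitudinal (traction) axis of the tissue strip; physical direction
vectors are written (vx, vy, vz); φ is the azimuth in the imaging plane
measured from +Y, θ the elevation out of the plane. The default voxel is
0.44 × 0.44 µm laterally with a 2 µm Z step — strongly anisotropic, which
shapes most of the design below.

## Preprocessing

Each Z-plane is equalized with CLAHE (`clip_limit` 0.08, a normalized clip
limit: the fraction of a tile's pixels one histogram bin may hold; tiles
target ~128 px). Equalization is deliberately strong so that deep, dim
planes contribute Z-band contrast; the cost is that empty tiles amplify
noise. Segmentation then quantizes intensities into K = 4 balanced clusters
with K-means and labels clusters Background or Tissue.

Three choices here were open and are worth recording:

* **Pre-cluster denoising.** K-means sees only intensities, and
  CLAHE-amplified background noise overlaps the Z-band intensity range
  pixel-wise. A light Gaussian blur (σ = 1 px) before clustering averages
  incoherent noise toward mid-grey while coherent bands stay bright, making
  the clusters separable. Without it, intensity clustering cannot segment a
  frame that mixes amplified background with tissue.
* **Cluster labelling.** The rule must adapt to frames with very different
  tissue quantity. We split the intensity-sorted clusters at the largest gap
  between consecutive cluster centres (dark side Background). A share-based
  rule (Background = the dark prefix holding ≥ 50% of pixels) was tried
  first and proved fragile: on realistic frames the background mass hovers
  near 50% and the label boundary flips with ~1% changes in cluster shares.
  The gap rule is scale-free and stable. Frames whose cluster centres span
  < 10% of the intensity range are declared tissue-free; frames with fewer
  distinct values than clusters fall back to an Otsu split.
* **Morphology.** Closing then opening with a 2 px disk bridges the ~4 px
  band period into solid cell footprints without merging distinct cells
  (~45 px wide); components under 100 px and holes up to 100 px are
  removed/filled. Masks are idempotent under a second refinement pass.

Planes whose raw 1st–99th percentile range is below 10% of the 8-bit range
carry no signal; equalizing them would only amplify noise, so they get an
empty mask directly.

## Orientation analysis

The masked volume is tiled with non-overlapping 16 µm cubic chunks
(8 × 36 × 36 voxels at the default voxel); partial edge chunks are dropped
and a chunk is analysed only if ≥ 80% of its voxels are in-mask.

Per chunk: the mean is subtracted (otherwise the DC term dominates every
energy ratio), the 3D FFT is centred, and the Z-frequency axis is
zero-padded from 8 to 36 planes. Padding makes the frequency lattice nearly
isotropic — Z bins of 1/(8·2 µm) = 0.0625 µm⁻¹ against XY bins of
1/(36·0.44 µm) = 0.0631 µm⁻¹ — so a *spherical* band-pass is meaningful; the
~1% residual anisotropy is accepted and a single Δf = 0.0631 µm⁻¹ is used
throughout. In the spatial domain the padding is exactly sinc interpolation
of the chunk to an isotropic 0.44 µm grid (a property the test suite checks
against an explicit DFT oracle).

The band-pass is a binary spherical shell on the padded grid: radii
(1/2.0)/Δf ≈ 8 px to (1/1.6)/Δf ≈ 10 px, mean (1/1.8)/Δf ≈ 9 px, rounded to
integers. Both the total PSD and the filtered PSD are smoothed with a
normalized 3 × 3 × 3 Gaussian kernel (σ = 0.8 px; by the convolution theorem
this apodizes the chunk radially, damping boundary leakage). Reflect padding
at grid edges keeps the kernel mass inside; the choice is inconsequential
because in-band energy sits ~9 px from the boundary.

**Sratio.** The reliability score is the in-band share of spectral energy,
band/total, with the DC bin excluded from the denominator. (An equivalent
printed form with a scale factor of 10 exists in the literature; any
constant factor cancels under the min–max normalization that follows, and we
report the plain energy ratio.) Scores are min–max normalized over the
tissue chunks of one sample and chunks above 0.14 are *reliable*.

Min–max is purely relative, so two guards accompany it: (i) a degenerate
sample in which all raw scores coincide normalizes to all-zero with a
warning; (ii) a chunk must also beat an absolute floor of twice the
flat-spectrum expectation (the shell's share of the informative Z-planes,
≈ 0.09) — otherwise a volume of pure noise would crown ~86% of its chunks
"reliable" simply because normalization spreads them over [0, 1]. For real
tissue with any quality gradient the floor is far below every genuine
Z-band chunk and never binds.

**Peak extraction.** The maximum voxel of the filtered PSD seeds an
intensity centroid over the 4 × 4 × 4 window anchored one voxel before the
maximum (the window is even, so some anchoring convention is required; ours
places the maximum at offset (1,1,1) and clips at grid edges). The vector
from the spectrum centre to the centroid is the cell axis; its length times
Δf is the Z-band frequency, its inverse the sarcomere period. The spectrum
is centrally symmetric, so vectors are flipped into the vy ≥ 0 hemisphere
(vy = 0 ties flip on vx) and ties between equal maxima resolve to the lowest
linear index — both for determinism.

**Outlier removal.** A single pass compares each reliable vector with the
mean direction of its reliable 26-neighbourhood: deviating by more than 45°
demands a normalized Sratio above 2 × 0.14, otherwise the record is flagged
an outlier and dropped. The 45°/2× quantification is a package decision (the
mechanism, neighbour comparison with a raised threshold, is standard); the
base threshold is applied first and raised once, in the same pass.

### Accuracy and the elevation limit

On noiseless synthetic gratings the estimator recovers the axis to ~1–2°
(mean); the azimuth error is uniform in φ. Elevation is different: bands
tilted by θ project onto the optical axis with period T/sin θ, and the 2 µm
Z step resolves that period only while it exceeds 2.3 × 2 µm (a Nyquist
factor of 2.3 covering sampling and PSF). With T = 1.8 µm this caps usable
elevations at asin(1.8/4.6) ≈ 23°; beyond it the spectral peak aliases and
elevation errors jump above 45°, which the rotation-accuracy experiment
reproduces as a sharp discontinuity between the ±20° and ±25° grid rows.
Disarray analyses should therefore be read as statements about fibres within
±23° of the imaging plane.

A brute-force oracle (1°-grid search maximizing in-band PSD energy along
rays) agrees with the centroid estimator to ~1° on average. Individual
gratings can disagree by up to ~3.5°: the centroid is a centre of mass, the
oracle an argmax, and spectral leakage skews the peak; the two estimators
answer slightly different questions about a skewed peak. The acceptance
suite therefore bounds the *mean* disagreement at 2°.

## Disarray statistics

The vector grid is tiled with m × m × m macrovoxels (m = 2…6, i.e.
32–96 µm sides at 16 µm chunks; partial macrovoxels at the far edges are
dropped; tiling starts at the grid origin). A macrovoxel is valid when at
least half of its slots hold reliable vectors. Local disarray is
1 − the mean resultant length of the unit vectors (in %), local alignment
the mean vy; global D and A average them over valid macrovoxels. Because
every vector lives in the vy ≥ 0 hemisphere, purely random orientations give
d ≈ 50%, perfect alignment 0%.

LDDs are fitted log-normally by moment matching on the log scale (the MLE
for a log-normal): μ = mean(ln d), σ = sd(ln d), with mode = exp(μ − σ²) and
sd² = (exp(σ²) − 1)·exp(2μ + σ²). Exact zeros (perfectly aligned
macrovoxels) have no logarithm; they are excluded and counted, and a fit is
refused below 20 positive values. Log-normality is tested with the
D'Agostino–Pearson omnibus K² on ln d — on ln d, not d, because the
hypothesis is log-normality. The K² transforms (D'Agostino's skewness,
Anscombe–Glynn kurtosis) are implemented in the package and verified against
an independent reference implementation to 10 decimal places.

Rendered disarray maps paint valid macrovoxels into a voxel grid, upsample
to chunk resolution and smooth with an isotropic Gaussian (σ = 10 µm
default); invalid regions render 0, and smoothing neither exceeds the map
maximum nor creates mass (interior integral preserved to < 1%).

## Synthetic phantoms and virtual samples

The phantom generator renders planes perpendicular to a stated axis with
period T (default 1.8 µm), duty cycle 0.45, anisotropic Gaussian PSF
(σz = 1.316 µm, i.e. the 3.1 µm axial FWHM / 2.355; lateral σ = 0.25 µm —
the axial figure is instrument-derived, the lateral one a typical two-photon
value) and additive Gaussian noise, quantized to 8 bits. The
rotation-accuracy experiment draws 20 random-phase gratings, applies every
rotation of a 13 × 13 (θ, φ) grid spanning ±30° in 5° steps (the grid size
matches the reported experiment; the range brackets the 20–23°
discontinuity), resamples each onto the anisotropic acquisition grid
(rotation centre snapped to a voxel centre so the identity rotation is
exact), applies the axial PSF in the laboratory frame, and runs the
orientation pipeline. Azimuth differences are wrapped to [−90°, 90°] since
orientations are axial.

The virtual-sample generator tiles a strip (default 1300 × 400 × 280 µm;
the calibration experiments in this package run a reduced
650 × 200 × 140 µm strip, whose ~3,900 chunks and 560 cells already give
stable D estimates) with a gapless lattice of 80 × 20 × 20 µm cells. Each
cell is cut from one shared base volume (default: a synthetic striated base,
80 × 80 × 66 µm, period 1.8 µm along Y — a stand-in for a real recording,
and labelled synthetic for that reason; a user TIFF base is accepted),
rotated by per-cell angles drawn from N(θ̄, σθ) and N(φ̄, σφ), re-blurred
along Z with σk = sqrt(σz² − σxy²) to mimic how the optical system sees a
rotated cell, and inserted; cell borders are smoothed with a σ = 1 px
Gaussian. One shared base (rather than random base offsets per cell) keeps
the only between-cell variation the rotation itself, which is what the
calibration needs.

Sweeping σθ = σφ over {0, 5, 10, 20}° maps true angular dispersion to
measured disarray: D rises monotonically (≈ 0, ≈ 0.5%, ≈ 1.4%, ≈ 5% at the
64 µm scale under the reduced-extent conditions), aligned samples give
near-zero D at every scale, and dispersed samples show modes that grow with
macrovoxel size. `match_dispersion()` inverts the map: it simulates
candidate dispersions and returns the one whose fitted LDD PDF is closest in
L2 on a fixed 0–50% grid (500 points) to an observed fit — the matching
criterion had to be fixed somehow, and L2 between unit-area fitted PDFs is
the simplest defensible choice.

## What the synthetic experiments do and do not show

The phantoms share the real signal's geometry (periodicity, anisotropic
PSF, 8-bit quantization, additive noise) but not its biology: no vessels,
nerves, fibrosis, intensity vignetting, stitching seams or deconvolution
artefacts. Passing the validation experiment therefore demonstrates the
estimator's geometric accuracy and its failure mode past the elevation
limit — not robustness to every real-tissue nuisance. Likewise the
virtual-sample calibration assumes rigid, lattice-packed cells with
independent orientations; real disarray is spatially correlated and mixes
cell-level with myofibril-level disorder. Error bounds from clean phantoms
are upper bounds on the method's intrinsic error, and real-data errors
reported for comparable pipelines are larger.

## Numerical and degenerate-input conventions

* All intensities live on the 0–255 scale at every stage; float TIFF pages
  store value/255 (the TIFF writer defines only [0, 1] float), and reading
  undoes the scaling.
* Constant frames equalize to themselves; all-zero chunks yield NA Sratio
  and no orientation; fields with no tissue warn and return empty.
* Chunk and macrovoxel tilings truncate at far edges; sample extents
  truncate to whole cells with a warning.
* Every stochastic step (noise, cell angles, validation phases) is governed
  by an explicit integer seed; identical seeds give byte-identical outputs.
* Test problem sizes: unit tests use 60–120-cell virtual samples
  (320 × 120 × 100 µm) and coarse validation grids; the acceptance suite
  runs the full 13 × 13 × 20 validation and four reduced-extent
  (650 × 200 × 140 µm) samples, the sizes at which the reported numbers are
  computed.

## Known limitations

Orientation is undefined past ~23° elevation by physics, not
implementation. Min–max Sratio normalization is sample-relative, so
homogeneous high-quality volumes mark their own weakest chunks unreliable
(~the threshold share); the absolute floor only protects against
structureless spectra. The segmentation labelling rule stands in for an
unpublished procedure and is documented as an approximation. Stitching,
deconvolution and PSF estimation are out of scope; the pipeline accepts
stacks as they come.
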
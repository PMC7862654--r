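---
title: "Ion beam tomography: models, reconstruction and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion beam tomography: models, reconstruction and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iontomo)
```

## The measurement being modeled

A focused primary ion beam (cesium or oxygen) rasters a cell on a silicon
substrate. Each scan sputters a few nanometres of material; the emitted
secondary ions are mass-analyzed pixel by pixel, so one raster scan produces
one image per mass channel, and ~1000 successive scans produce a depth series
through the whole cell. Two physical facts shape everything downstream:

* the lateral resolution is set by the beam width (100–200 nm for whole-cell
  scans), well above the pixel size (50–100 nm), so images are blurred; and
* ions are collected not only from the freshly etched plane but from material
  up to ~100 nm below it, so each slice integrates a slab of the object.

`iontomo` implements the full computational chain for such data: a physical
forward simulator, sliding-window depth binning, Lucy–Richardson
deconvolution with a beam-current-derived ("blind") PSF, localization-based
reconstruction (SILM), fiducial drift registration, resolution and
similarity metrics, and a spatial-statistics layer.

## Forward model

The simulator generates the detected image as

> counts = Poisson( efficiency × (object ⊗ PSF) × gamma )

per slice, channel and pixel:

* **Object** (`object_volume()`): point emitters, uniform spheres
  (isotope-doped nanotags) and half-plane layers (edge targets). A point with
  `z_nm = NA` is present at every depth.
* **PSF** (`psf_model()`): separable — a lateral Gaussian parameterized by
  FWHM (`sigma = FWHM / 2.3548`) and a uniform axial box of
  `axial_extent_nm` (default 100 nm, the stated ion penetration depth).
  Slice `s` integrates object content over `[z_s, z_s + axial_extent)` with
  `z_s = (s - 1) * z_step`. A uniform axial profile is the simplest model
  consistent with sub-surface collection; a decaying profile would only
  reweight the slab integral.
* **Noise** (`noise_model()`): i.i.d. multiplicative gamma factors with the
  mean pinned to 1 (shape `k`, scale `1/k`; default `k = 3`) so that the
  extraction efficiency keeps its interpretation as the expected fraction of
  emitted material registered (3% by default); an optional uniform
  dark-count floor (default 0, the background in ion imaging is very low);
  and a Poisson ion-counting stage (`counting = TRUE` by default). The
  counting stage preserves the model mean exactly, and it is what produces
  the sparse, small-integer pixel values (a few counts per pixel) that real
  low-current scans show and that localization analysis feeds on. Setting
  `noise = NULL` gives the noiseless expectation image, used by the exact
  contracts in the test suite.

Spheres are rasterized by the analytic chord length of the slab–sphere
intersection, averaged over a 3×3 sub-pixel grid to avoid aliasing. Pixel
coordinates are 0-based and pixel-center throughout: pixel `(i, j)` (row,
column) is centered at `((j - 0.5) dx, (i - 0.5) dy)` nanometres; this
convention is what makes sub-pixel localization unambiguous and is asserted
by round-trip tests.

## Study fixtures

The generator's defaults are the study conditions, chosen once:

* `six_point_fixture()` — six collinear point sources 200 nm apart, imaged
  with a 120 nm beam on 50 nm pixels (`six_point_geometry()`): the canonical
  validation target for binning + deconvolution.
* `edge_fixture()` — a uniform half-plane, the edge-spread resolution target.
* `nanotag_fixture()` — non-overlapping spheres with diameters drawn from
  N(109.8, 17.6²) nm (truncated at zero), emitting identically in every
  channel. The default emission density (9 counts per nm of intersected
  depth before efficiency) puts the expected peak pixel near 9 counts for a
  mean-diameter tag at 3% efficiency on 50 nm pixels — the sub-10-counts
  regime quoted for real scans.
* `nanotag_pair_fixture()` — two small spheres at a chosen spacing, for
  sub-beam-width separation experiments.
* `pulse_chase_fixture()` — two channels sharing a chosen fraction of source
  positions, emulating short-chase (high overlap) versus long-chase (low
  overlap) double labeling.
* `apply_drift()` — per-slice lateral offsets (bilinear interpolation, which
  keeps counts non-negative; a spline would overshoot below zero) plus an
  optional bright fiducial disc in a dedicated channel.

What the simulator does **not** emulate: matrix effects and local
sensitivity variations, charging, detector dead time, correlated
(object-level) brightness fluctuations, and non-rigid drift. Tests passing
on these fixtures therefore validate the algorithms under the stated noise
model, not instrument-specific artifacts.

## Reconstruction

**Sliding-window binning** (`sliding_window_sum()`): output slice `t` is the
sum of input slices `t … t+n−1`, so a depth series of length `L` becomes
`L − n + 1` slices. Signal-to-noise (`snr_db()`) rises with `n` while axial
sampling is preserved. The SNR is `20·log10(mu_signal / rms_background)`;
note the *squared* deviation under the radical — the unsquared mean
deviation is identically zero, so the RMS reading is the only one that
yields finite decibel values.

**Deconvolution** (`deconvolve_stack()`): each binned slice is deblurred by
the multiplicative Lucy–Richardson update with a Gaussian PSF whose width
comes from the recorded beam current (`blind_psf_from_current()`:
log-linear from 0.2 pA → 100 nm to 4 pA → 200 nm, clamped outside with a
warning — the calibration states only the endpoints, so the interior map is
a package choice and every run logs the width used). Numerical choices that
matter:

* Convolution and the correlation step use dense 1-D operators with
  half-sample symmetric boundary extension. With a symmetric kernel this
  operator matrix is itself symmetric, so the correlation step is the exact
  adjoint of the convolution step and the estimate's total flux equals the
  data flux after every iteration to floating-point precision — the
  conservation property the tests assert at 1e-6 is actually exact.
* The ratio denominator is floored at 1e-12 to avoid 0/0 in dark regions.
* Default 5 iterations (middle of the useful 3–10 band); iterating further
  sharpens but amplifies noise.
* The light 2×2 post-filter (`postfilter()`) is a Gaussian of
  `sigma = size/2.355` px or a 3×3 median, applied per slice after the
  iterations.

The update runs in 2D per binned slice: the axial blur has already been
shaped by the binning window, and per-slice processing keeps memory bounded.

**SILM** (`upsample()`, `detect_and_localize()`, `render_silm()`): raw
slices are bilinearly interpolated 3× (field semantics — values are
interpolated, not redistributed; thresholds are computed on the same field),
candidates are local maxima above `median + k·MAD` (k = 4; MAD is robust to
the sparse bright events themselves), and each candidate is localized by an
iterative Gaussian-mask weighted least-squares fit. The mask fit was chosen
over a free-parameter Gaussian fit after simulation showed 2–3× lower
position scatter under multiplicative noise at low counts; its fixed point
is the closed-form weighted least-squares position. The mask width defaults
to the PSF sigma and accepts a spot-matched override
(`sqrt(sigma_psf² + (d/4)²)` for a tag of known diameter `d`). Detections
within half a beam width merge to the brighter one; rendering places one
unit-mass Gaussian per localization, scaled by its counts (or unit weight),
so rendered mass equals summed counts exactly.

The reported precision per localization is
`sqrt(sigma_psf²/N + sigma_psf²/(k_gamma · 4π sigma_px²))` — the counting
term plus a multiplicative-noise floor over the effective pixel count. It is
an estimate; the test suite validates it against Monte-Carlo scatter within
a factor of two. For precision analyses, localizations below ~20
raw-equivalent integrated counts are excluded (`min_counts`): simulation
shows they are noise-dominated (scatter roughly doubles when they are
included), which matches the guidance that usable events sit slightly above
the background threshold.

**A documented limitation.** With i.i.d. per-pixel noise, a tag pair
separated by less than twice the PSF sigma has an expected image that is
essentially unimodal, and no per-slice localization scheme can assign counts
to one emitter or the other: the localization density inherits the blur.
Splitting such pairs requires object-level intensity fluctuations between
slices (the analogue of fluorophore blinking), which the pixel-i.i.d. noise
model deliberately excludes. The corresponding end-to-end expectation is
kept in the acceptance suite as a faithful, currently failing check rather
than weakened; the cross-channel agreement property (SILM SSIM at least the
raw-sum SSIM on nanotag fields) holds and is asserted.

**Drift registration** (`estimate_drift()`, `apply_correction()`): offsets
are estimated per slice against slice 1 by FFT cross-correlation with
quadratic sub-pixel peak interpolation (a fixed reference avoids error
accumulation; previous-slice chaining is deliberately not the default, and
an integer-only mode exists). Flat fiducial slices get interpolated offsets
and are flagged. Correction applies the negated trace to every channel with
an exact Fourier phase-ramp translation: unlike interpolation it does not
smooth, so correcting a small sub-pixel offset can never reduce the
correlation against the reference; wrapped margins are zeroed and negative
ringing is clamped to keep counts non-negative.

## Quantification

* `cc2d()` — the plain product-moment correlation of two images; constant
  images are an error, not a silent NaN. `colocalization_series()` computes
  it per depth (skipping and counting constant slices) and summarizes as a
  box-plot five-number report; `compare_conditions()` is the two-sided
  Wilcoxon rank-sum test between two series.
* `ssim()` — both images are min-max normalized to [0, 1], then the standard
  stabilized structural-similarity form with `C1 = (0.01)²`, `C2 = (0.03)²`
  on `L = 1` is computed from global statistics (the primary value), with a
  windowed mean (11-tap Gaussian, sigma 1.5) reported alongside. The
  denominator uses `mu_x² + mu_y² + C1`; the version without the `+` that
  sometimes appears in print is a typographical defect, as only the
  stabilized form is consistent with the cited metric.
* `edge_resolution()` — least-squares fit of
  `offset + amplitude · Φ((x − center)/sigma)` to an edge scan; the
  88–12% resolution is `2 · 1.17499 · sigma = 2.34998 sigma`, the FWHM of
  the effective Gaussian PSF. This closed form is the bridge that lets
  resolution claims be tested on synthetic edges. Near-ideal steps defeat
  the erf fit (the Jacobian in sigma degenerates), so a monotone profile
  falls back to direct 12%/88% level crossings; non-monotone failures raise
  an error with the residual report.
* Spatial layer: `fcm_states()` (full fuzzy C-means, fuzzifier `m = 2`,
  tolerance 1e-5, max 300 iterations — all three unstated in the source
  material and fixed here; hard labels are affine-invariant by
  construction), `kmeans3d()` (per-channel standardization then [0, 1]
  min-max normalization, k-means++ initialization, Lloyd iterations,
  farthest-point re-seeding of empty clusters; z-scores for the heatmaps are
  computed on the standardized features used for clustering),
  `block_peaks()` (per-block `median + 4·MAD` thresholds), exact
  `peak_pairwise_distances()` with anisotropic voxel scaling,
  `euclid_hierarchical()` (average linkage, seeded subsampling cap of 2000
  voxels — the full voxel count would be quadratically infeasible),
  `channel_correlation_matrix()` (Pearson; the association matrix clips
  negatives for chord-diagram export, the drawing itself being out of
  scope), and `delaunay_neighborhoods()` (in-package Bowyer–Watson
  triangulation in 2D and 3D; exactly degenerate configurations are
  perturbed by a deterministic seeded jitter of 1e-6 px and flagged).

## Reproducibility plumbing

Stacks are written as one multi-page 16-bit grayscale TIFF per mass channel
plus a JSON sidecar carrying the geometry, channel labels, seed and
provenance; integer counts round-trip bit-exactly, and reading never guesses
missing geometry. `run_pipeline()` composes the stages from a YAML
configuration, derives per-stage seeds from the global seed
(`stage_seed()`, `seed + 1000·stage`), and writes a manifest recording
versions, seeds and parameters; identical configuration and seed give
identical outputs. A thin command-line front end is installed at
`inst/cli/ibt.R`.

## Problem sizes used in validation

The test-suite and acceptance fixtures use 64–128 px fields, 20–70 slices,
and 3–20 replicate seeds — sizes at which every oracle (literal
transcriptions, brute-force enumerations, closed forms, planted partitions)
can be evaluated exactly alongside the implementation. The statistical
properties (recovery rates, precision medians, planted-partition agreement)
were chosen to be stable across seeds at these sizes, and the same fixtures
scale linearly to full 256 px × 1000-slice acquisitions.
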
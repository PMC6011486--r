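---
title: "Methods: aortic stiffness from 4D flow CMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aortic stiffness from 4D flow CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortapwv)
```

## The measurement problem

Aortic stiffness rises with age as elastin in the vessel wall degrades, and
it is an independent predictor of cardiovascular events. Two imaging-based
stiffness markers are computed here from cardiovascular MR:

* **Pulse wave velocity (PWV)**, the speed at which the systolic flow wave
  travels down the aorta. A stiff tube conducts the wave faster
  (Moens–Korteweg). PWV is a *global* marker: it integrates wall properties
  over the whole thoracic aorta.
* **The distensibility coefficient (DC)**, the relative change of a
  cross-section per unit pulse pressure, `DC = (2·Δd/Dd) / ΔP`, reported in
  10⁻³/kPa. DC is a *local* marker, computed from a 2D CINE series of one
  plane, and falls as the vessel stiffens — so DC and PWV should correlate
  negatively across a cohort.

From 4D flow CMR (time-resolved, three-directionally velocity-encoded
phase-contrast imaging of the whole thoracic aorta) PWV is estimated by:

1. correcting velocity aliasing and eddy-current offsets,
2. segmenting the lumen and extracting a centerline between two
   user-supplied seed points,
3. distributing analysis planes normal to the centerline at a fixed
   arc-length spacing (5 mm),
4. integrating the through-plane flow rate Q(t) on each plane,
5. detecting the wave arrival per plane by three algorithms —
   time-to-foot (TTF), half-peak (50% rule) and cross-correlation (XCor) —
   and
6. fitting arrival time against arc length by ordinary least squares;
   PWV is the inverse slope.

Because no subject data are distributed, the package ships phantom
generators whose ground truth is known analytically; all quantitative
claims below are backed by the test suite, which recomputes them.

## Wave-arrival definitions and numerical choices

All three detectors operate on the plane flow waveform `Q(t)` sampled at
the acquisition's temporal resolution (20 ms by default).

* **Upstroke window.** The systolic upstroke is the sample run from the
  last pre-peak crossing of a low threshold (10% of the pre-peak range
  above the minimum) up to the global peak. This is unambiguous for
  single-pulse cardiac waveforms; multi-peaked flow (severe regurgitation)
  is out of scope.
* **TTF** is the intersection of the diastolic baseline (median of the
  pre-upstroke samples) with a straight line fitted to the 20–80% portion
  of the upstroke. The name says only "foot"; the 20–80% regression line is
  the conventional operationalisation and is stated here so results are
  reproducible. When the upstroke is so steep that no sample falls inside
  the band, the line through the interpolated 20% and 80% crossing times is
  used instead, which keeps the estimate continuous in the data.
* **Half-peak** is the first upstroke crossing of
  `baseline + 0.5·(peak − baseline)`, linearly interpolated between the
  bracketing samples.
* **XCor** maximises the normalised cross-correlation against the most
  proximal plane's waveform over integer lags, then refines the lag with a
  parabola through the peak and its two neighbours. The reference plane is
  the first plane; since a constant reference shift is absorbed by the
  regression intercept, the choice does not affect the slope.
* **Regression orientation.** Arrival time is regressed *on* distance
  (slope = 1/PWV), not the reverse: arc length along the centerline is the
  low-error variable, while arrival times carry the noise. The orientation
  matters under noise and is recorded in the output.
* **Validity.** A non-positive fitted slope (wave apparently travelling
  backwards) flags the estimate invalid rather than returning a negative
  velocity. An optional robust mode drops planes with residuals beyond 3
  median absolute deviations and refits once; it is off by default because
  the transit-time fit on clean data should not silently reweight.

A deliberate integration detail: the flow integral uses the lumen
cross-section *dilated by one grid cell* (a partial-volume guard band).
Trilinear sampling spreads the flux of wall-adjacent voxels across the
contour; clipping at the 0.5 mask level loses a few percent of plug flow,
while the guard band recovers it. The band adds only near-zero samples on
clean data and zero-mean noise otherwise, and the arrival detectors are
scale-invariant in Q anyway.

## Geometry

The centerline is extracted as the shortest path between the seed points in
a voxel graph whose edge weights are `step length / depth²`, where depth is
the erosion distance to the vessel wall — the path is pulled onto the
medial axis. The raw voxel path is smoothed per coordinate by a cubic
smoothing spline against arc length (one degree of freedom per ~5 mm) and
resampled at 1 mm. The df default balances two error modes measured on
analytic tubes: too stiff a spline cuts the arch corner and shortens the
path (biasing PWV low, since distances enter the slope), too loose a spline
follows voxel zigzag and lengthens it. At the default, a 290 mm candy-cane
centerline is recovered to ~0.3% and a semicircular tube's arc length to
~1%; transit distances are arc lengths along this centerline, never chord
lengths.

Planes are placed at `s = s_start, s_start + 5 mm, …`, giving
`floor(span/spacing) + 1` planes — both endpoints included, which
reproduces 61 planes for a 300 mm segment at 5 mm. A spacing longer than
the segment yields a single plane plus a warning; the PWV fit then rejects
with a clear error instead of fabricating planes. Each plane's in-plane
grid is square with half-width twice the estimated lumen radius at the
finest voxel pitch, and the plane's lumen is the connected component of the
sampled mask containing the centerline point.

## Preprocessing models

* **Phase unwrapping** is temporal: each voxel is anchored at phase 1 and
  later phases are shifted by the multiple of 2·venc that minimises the
  jump to the previous phase. This matches the dominant aliasing mode of
  velocity-encoded data (brief systolic overshoot beyond venc) and is the
  identity on wrap-free voxels. It cannot fix a voxel that is already
  aliased at phase 1 (a diastolic velocity beyond venc), which does not
  occur at the default venc = 1.5 m/s.
* **Eddy-current correction** fits a first-order spatial polynomial
  (offset + linear gradients per component) to the temporal-mean velocity
  of static tissue and subtracts it everywhere. First-order is the minimal
  standard model; the fit is linear least squares, so corrections are
  additive in the injected offsets (a property the tests exercise).
* **Segmentation** stands in for an interactive step: threshold the
  temporal-maximum speed at a fraction (default 0.2) of its global maximum,
  keep the largest connected component (or the one containing an optional
  seed point), and close one voxel morphologically. On noise-free phantoms
  the Dice overlap with the true lumen exceeds 0.99; the mask is static
  over the cycle, as the downstream plane machinery assumes.

## Contour propagation and the distensibility coefficient

Vessel motion in the CINE series is estimated by a multi-scale phase-based
registration: oriented log-Gabor quadrature filters (four orientations,
wavelengths 16 → 8 → 4 px) yield local phases whose frame-to-frame
differences are proportional to displacement along each orientation,
independent of local intensity; a per-pixel weighted least squares merges
the orientations, normalized convolution smooths the field (σ = 2.5 px),
and three warp-and-re-estimate iterations per scale accumulate the result
coarse-to-fine. This is a fixed-schedule simplification of Morphon-style
registration without certainty propagation across scales. Displacement
fields between consecutive frames are applied serially to carry the
reference contour (a polygon with sub-pixel vertices) through the cycle.

Two numerical findings shaped this module:

* **Warping must be band-faithful.** The vessel edge is only marginally
  sampled (PSF ≈ 1 px FWHM at 1.8 mm pixels), so bilinear — and even
  bicubic — resampling inside the warp loop slightly erodes curved edges;
  the phase step reads that erosion as genuine outward motion, biasing the
  converged displacement by 10–25% of the per-step motion. The warp
  therefore samples a sinc-upsampled (FFT zero-padded, 4×) image, which
  removes the artifact. FFT periodicity produces wrap-around ripple at the
  image border, far from any usable contour.
* **The apparent edge of a blurred disk is not its geometric edge.** The
  half-level contour of a disk of radius r imaged with PSF σ sits near
  `r − σ²/(2r)`, and its motion under pulsation slightly exceeds the
  geometric boundary motion. Any faithful intensity tracker inherits this
  inflation; at the defaults (σ ≈ 0.7 px total edge width, r ≈ 6–8 px) it
  is a low-single-digit percentage of Δd.

Areas of polygon contours are computed by the shoelace formula rather than
by rasterise-and-count: the vertices are sub-pixel, and rasterisation
quantisation would add frame-to-frame area jitter larger than the diameter
signal at realistic excursions. Mask contours (e.g. hand-drawn ROIs) use
pixel summation. The equivalent diameter is `2·sqrt(A/π)`; `Dd` is the
diameter at the end-diastolic frame and `Δd = max_k d_k − Dd`.

The end-diastolic frame defaults to the frame of minimum diameter — the
unambiguous reading of "end-diastolic" — but is configurable, and the
pipeline caller should pass the frame the reference ROI was drawn on when
it is known: picking the minimum of a noisy curve deflates `Dd` by an
extreme-value bias and correspondingly inflates `Δd`. The pressure bridge
is fixed at 1 mmHg = 0.133322 kPa and echoed in the output; systolic and
diastolic pressures may each be given as pre/post-scan pairs, which are
averaged.

**Resolution floor.** At 1.8 mm pixels, 25 phases and intensity noise sd
0.02 (SNR ≈ 40), the per-frame equivalent-diameter error is ≈ 0.03–0.06 px
and the resulting precision of `Δd = max − reference` is ≈ 0.05 mm — an
edge-localisation information limit combined with the extreme-value
statistics of the maximum, not a fixable implementation detail. Excursions
of 1 mm therefore cannot be recovered to 5% under these acquisition
settings, while 1.5 mm and above can; the validation grid spans
Dd ∈ {20, 24, 30} mm × Δd ∈ {1.5, 2, 3} mm, which covers the
physiological DC range ≈ 12–56 × 10⁻³/kPa.

## What the phantoms emulate — and what they do not

The **flow phantom** is a candy-cane tube (straight ascending limb,
semicircular arch, straight descending limb; ≈ 300 mm centerline, 12 mm
lumen radius) carrying a raised-cosine systolic pulse that propagates at a
prescribed PWV; voxels are 2.5 × 2.1 × 2.5 mm, dt = 20 ms, venc = 1.5 m/s,
matching the target acquisition. The waveform (onset 60 ms, upstroke 80 ms,
downstroke 120 ms, peak 1 m/s, plug or parabolic profile) is a stand-in:
the pulse shape of real subjects is unknown and, crucially, real pulses
*disperse and steepen* along the aorta, while the phantom's translates
rigidly. Passing tests therefore demonstrate *algorithmic* fidelity
(geometry, integration, arrival detection, regression), not physiological
fidelity; reflected waves, turbulence, wall motion and k-space physics are
all absent. Optional artifacts — Gaussian velocity noise, first-order
eddy-current offsets, and venc wrapping — are generated exactly as the
corresponding corrections assume, which is what makes those corrections
testable in isolation.

The **CINE phantom** is a pulsating anti-aliased disk with Gaussian PSF and
noise; it omits surrounding anatomy, through-plane motion and flow-related
signal variation. The **cohort simulator** draws ages uniformly within six
decade-by-sex cells (n = 126 total, the reference population's layout) and
generates PWV from the linear model `1.51 + 0.080·age + 0.53·male` with
residual sd 0.77 m/s; optional covariates (blood pressures, diameters, DC)
follow linear links with age chosen so that the qualitative cohort
signatures — DC falling while PWV rises — hold.

## Problem sizes and runtimes

The shipped tests run the full image pipeline at the sizes above: one
noiseless phantom plus 20 noisy replicates (velocity noise 5% of peak) for
PWV recovery (each ≈ 45 × 21 × 83 voxels × 20 phases, ~55 planes), nine
(Dd, Δd) CINE cells × 3 noise seeds for DC recovery (64 × 64 × 25 frames),
and 200 simulated cohorts for the reference regression. The whole suite
completes in a few minutes on one CPU. The statistics-only acceptance
script (`scripts/acceptance.R`) runs in well under a minute.

## Known limitations

* Per-segment (local) PWV is not computed; the transit-time fit assumes a
  single global wave speed along the thoracic aorta.
* The centerline extractor assumes an unbranched tube; supra-aortic
  branches are not modelled and would perturb both segmentation and the
  medial path near the arch.
* The Wilcoxon comparison is strictly paired (the three algorithms are run
  on the same subjects); an unpaired mode is deliberately not offered.
* Adjusted-correlation p-values ignore the degrees of freedom consumed by
  the prior age/sex regressions; with n ≥ ~100 the approximation is
  immaterial, at small n it is slightly anti-conservative.
* No multiple-testing correction is applied by default, matching the
  descriptive reference-value setting; `stats::p.adjust` composes directly
  with the returned p-values where screening is intended.
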
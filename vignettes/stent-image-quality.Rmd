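---
title: "Quantifying stent blooming across CT reconstruction kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stent blooming across CT reconstruction kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctstent)
```

## The measurement problem

Metallic stent struts bloom in CT: reconstruction blur and partial-volume
averaging enlarge them, and in small vessels the bloomed struts can
obscure the contrast-filled lumen entirely.  Sharp vascular reconstruction
kernels reduce blooming at the price of noise.  `ctstent` quantifies this
trade-off with three instruments — the edge-rise-slope (ERS) profile
analysis, the four-ROI coefficient of variation (CV), and the AAPM TG220
water-equivalent diameter — plus the ordinal statistics used to compare
reconstructions in multi-reader studies.  A digital stent-in-phantom
simulator supplies controlled test volumes so every stage of the pipeline
can be validated against analytic ground truth.

## The phantom and stent model

The simulated object is a silicone tube filled with iodinated contrast
diluted to 300 HU, mounted in water, with a stent expanded against the
tube's lumen wall.  The simulator grids only the sub-volume around the
stent; the water margin (default 17 mm transverse, 10 mm axial beyond the
stent) is wide enough for both the profile baseline and the background
ROIs.

The stent is a thin cylindrical shell at the lumen radius:

* **bare stents** — evenly spaced strut rings of square cross-section
  (`strut_thickness`, default 0.3 mm) at an axial pitch of twice the strut
  thickness, centered within the stent span so the strut envelope is
  symmetric;
* **covered stents** — a continuous membrane of the same thickness at
  `cover_hu`.

Real strut architecture (helical cells, crowns, connectors) is not
modeled; rings are the simplest geometry that produces the two-peak
transverse profile the analysis needs, with a realistic ~50% strut duty
cycle along the axis.

Material attenuations default to water −4 HU, lumen 300 HU, silicone wall
100 HU, struts 3000 HU; all are overridable.  Two of these deserve
comment:

* **Struts at 3000 HU.**  Solid metal at 120 kVp reads in the thousands of
  HU (scanners commonly clip at 3071).  The value matters: with struts
  only ~4× the contrast level, the blurred strut bump of a 3 mm stent
  sinks below the blurred contrast dome under a soft kernel and the
  profile becomes unimodal — which is not how metallic stents image, and
  would make edge analysis impossible exactly where blooming matters most.
* **Water at −4 HU.**  Tap water typically reads a few HU below zero.  The
  choice is load-bearing for CV: with a mean of exactly 0 HU the CV
  denominator is a pure noise average and CV degenerates to an arbitrary
  huge ratio; a slightly negative mean gives the stable, negative,
  noise-proportional CV readings seen in practice.

## Kernel emulation

A reconstruction is emulated by three parameters: an isotropic Gaussian
point-spread blur `psf_sigma`, the reconstruction grid (in-plane
`pixel_size`; slices of `slice_thickness` box-averaged and sampled every
`increment`), and additive white noise `noise_sd` on the reconstructed
grid.  The default family is

| kernel    | σ (mm) | noise SD (HU) | pixels (mm) | slices (mm)     |
|-----------|--------|---------------|-------------|-----------------|
| EID-Bv40  | 0.70   | 14            | 0.6         | 0.5 every 0.5   |
| PCD-Bv40  | 0.65   | 12            | 0.4         | 0.4 every 0.3   |
| PCD-Bv48  | 0.48   | 18            | 0.4         | 0.4 every 0.3   |
| PCD-Bv56  | 0.30   | 26            | 0.4         | 0.4 every 0.3   |

These are stand-in calibrations, not scanner measurements.  They encode
the two orderings that define a kernel family — blur strictly decreasing
and noise strictly increasing with kernel strength (validated by the
`kernel_model` constructor) — with 10–90% edge rises of roughly 0.7 to
1.6 mm.  The soft end was deliberately kept below σ ≈ 0.8 mm: beyond
that, a 3 mm stent's strut peaks merge with its contrast dome into a
single maximum and the profile analysis has nothing to measure, whereas
actual soft vascular kernels do preserve the two-peak signature on 3 mm
stents.

Blur-then-downsample is implemented exactly as one separable linear
operator per axis (a box-average matrix composed with a Gaussian
convolution matrix, truncation-renormalized at the grid edges).  Two
consequences: the noise-free output is a convex combination of material
values (no ringing, no overshoot), and `simulate_scan()` can stream the
computation through the phantom's axial structure — only two distinct
transverse material planes exist — so a full 12-stent × 4-kernel
experiment simulates in about half a minute without ever materializing
the supersampled grid.  `apply_kernel()` on a materialized
`build_material_map()` gives identical results (tested) for workflows
that need the intermediate.

The output grid is centered on the field of view so that an object on the
grid center stays on a pixel center after downsampling; the world origin
(and `axis_hint`) is shifted accordingly.  Without this quarter-pixel
alignment the sampled annulus is systematically lopsided, which biases
axis detection.

Supersampling defaults to 4× the target pixel size; noise is drawn once
per output voxel from a seeded generator (the caller's RNG state is
preserved), making volumes bit-reproducible for a given
(spec, geometry, kernel, seed).

## The profile pipeline

`analyze_stent()` chains, with stage-labeled errors:

1. **Axis**: taken from the volume's `axis_hint`, or detected by
   thresholding midway between the lumen mode and the strut maximum,
   computing attenuation-weighted per-slice centroids (slices with fewer
   than a quarter of the maximum supra-threshold count are dropped — end
   slices and noise specks give unstable centroids), and fitting the
   first principal component.
2. **Section**: the plane containing the axis is resampled by trilinear
   interpolation; columns sample the transverse coordinate at a quarter
   of the pixel size, zero on the axis.
3. **Extent**: the per-row maximum, smoothed over ~1 mm to suppress the
   ring/gap oscillation, crosses halfway between the tube level (median
   of the lowest 15% of rows) and the stent level; first-to-last crossing
   rows bound the stent, then one slice thickness is trimmed at each end
   against end-cap partial volume.
4. **Profiles**: one per row inside the extent; their pointwise mean is
   the measured profile (noise shrinks as 1/√n_rows).
5. **Features**: baseline = average of the medians of the outer 20% of
   positions on each side; the two peaks are the global maxima left and
   right of the axis, both required to rise at least three noise floors
   above baseline; the lumen minimum is the global minimum strictly
   between them.
6. **Edge metrics**: per side, HU10/HU90 are 10%/90% of the rise from
   baseline to that side's peak.  Relative-to-baseline levels are used
   because with a nonzero water background absolute percentages of the
   maximum would be ill-defined; and per-side peaks are used because the
   two edges of an asymmetric profile should be scored against their own
   maxima.  Crossings are found scanning outward from the peak — the 90%
   crossing first, then the 10% crossing beyond it — with linear
   sub-sample interpolation; on a monotone flank these crossings are
   unique, and under residual noise the scan order resolves ties toward
   the peak.  ERD is the distance between crossings, ERS their HU
   difference over ERD, and `ers_mean` averages the two sides.  The
   falling inner flank into the contrast is deliberately not part of ERS;
   it is summarized by the lumen minimum instead.

For an ideal linear ramp the measured ERS equals the ramp slope exactly
(interpolation on samples of a line is exact); for a Gaussian-blurred
step, ERD = 2 × 1.28155 σ = 2.5631 σ.  Both are enforced as oracles in
the test suite at 1% (erf) and 10⁻⁶ relative (ramp).

**Blur-width recovery.**  ERD/2.5631 estimates σ only where the edge is an
isolated step: a thin strut shell truncates the flank (the profile is a
blurred pulse, not a blurred step) and biases ERD low by 15–30%.  The
package therefore validates recovery on a *thick-membrane* covered 8 mm
test object (3 mm membrane at 350 HU, no tube wall): the membrane is
thick relative to every tested σ and only slightly above the contrast
level, so the outer edge is an isolated ~354 HU step while the shallow
lumen dip still gives the two-peak signature.  On this object σ̂ recovers
σ ∈ {0.3, 0.5, 0.8} mm within 3%.  This is a validation of the estimator
in its asymptotic regime, not a claim that σ̂ is unbiased on thin-strut
stents.

## CV and water-equivalent diameter

`place_background_rois()` puts four circular 100 mm² ROIs (radius
5.64 mm) at 0°/90°/180°/270° on the mid-stent axial slice, their nearest
edges 5 mm from the stent's outer wall, and errors naming the required
margin if the water ring cannot hold them.  A voxel belongs to a ROI if
its center lies inside the circle.  CV = σ̄/mean; both the signed value
and |CV| are reported, because with a near-zero denominator the sign
carries no quality information while the magnitude tracks noise.

`water_equivalent_diameter()` accepts an explicit mask or a whole slice
including surrounding air (air voxels contribute area but almost no
attenuation and cancel in the limit, which the tests verify), reports
D_W in cm, and rejects regions with mean HU below −1000 as unphysical.

## Reader statistics

The statistics layer operates on complete long-format score tables
(reader × stent × reconstruction × criterion, scores 1–5):

* **Friedman** rank ANOVA with blocks = (reader, stent) pairs and
  treatments = reconstructions, average ranks for ties and the
  tie-corrected χ² statistic.  Blocking on (reader, stent) uses all data
  symmetrically; a fully tied table returns Q = 0, p = 1.
* **Pairwise Wilcoxon rank-sum** with continuity correction and
  tie-corrected normal variance, Bonferroni-corrected
  (min(1, m·p)).  The rank-sum test is the stated post-hoc method even
  though the design is paired; a signed-rank variant is available via
  `paired = TRUE` rather than silently substituted.
* **Fleiss' κ** over items = (stent, reconstruction, criterion) cells,
  banded poor < 0.20 ≤ fair < 0.40 ≤ moderate < 0.60 ≤ substantial ≤
  0.80 < perfect.
* **Repeated-measures ANOVA** (subjects = stents, within-factor =
  reconstruction) by direct sum-of-squares partition, cross-checked in
  the tests against `aov()` with an error stratum.

The synthetic reading model generates scores by discretizing a latent
quality — a per-reconstruction mean, plus a per-stent offset shared by
all readers (SD 0.8), plus reader bias, plus independent noise (SD 0.5) —
through cutpoints at 1.5/2.5/3.5/4.5.  The two dispersions were calibrated
together so generated tables show the inter-reader agreement level typical
of ordinal image-quality reading (Fleiss' κ ≈ 0.25–0.33, the fair band):
without the shared stent effect, agreement beyond chance collapses
(κ ≈ 0.02), because exact-category agreement needs a common item-level
signal, not just a common reconstruction ordering.

## Problem sizes and numerical choices

The shipped experiment sizes are deliberate desk-scale choices: 12 stents
× 4 kernels at 4× supersampling (~30 s), blur recovery on 0.15 mm pixels
(~10 s), 1000-replicate null simulations for test size (~10 s).  Fixed
numerical conventions: voxel centers at (i − 0.5) × spacing; trilinear
interpolation clamps at the half-voxel border (the clamped fringe is
always water); Gaussian operators are truncation-renormalized per row;
the Friedman statistic returns Q = 0 when the tie-corrected denominator
vanishes; CV errors at an exactly zero mean rather than returning ±Inf.

## What passing tests do and do not show

The simulator reproduces the *structure* the analysis assumes — two-peak
profiles, kernel-ordered edge widths, calibrated white noise, latent-
driven ordinal scores — so green tests certify the measurement machinery:
oracles for every estimator, orderings for every monotone relationship,
exact determinism.  They do not certify scanner realism: real
reconstruction kernels are not Gaussian (their PSFs ring), CT noise is
spatially correlated with a kernel-dependent spectrum, iterative
reconstruction is nonlinear, real struts are thinner and helical, and
contrast flows.  Absolute ERS/CV values from the simulator are therefore
internally consistent but not comparable to any particular scanner's
numbers; orderings and the estimator properties are the transferable
results.  Motion, spectral/monoenergetic reconstruction and in-stent
restenosis detection are out of scope.
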
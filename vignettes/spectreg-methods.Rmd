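---
title: "Registration-based comparison of knee SPECT/CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration-based comparison of knee SPECT/CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After unicondylar knee arthroplasty (UKA), bone remodelling around the
implant can be observed on hybrid SPECT/CT: the CT carries the anatomy, the
SPECT the uptake of a bone-seeking radiotracer (a proxy for osteoblastic
activity). Pre- and post-operative scans of one patient, and scans of
different patients, are not spatially aligned — the patient lies differently
in the scanner and anthropometry varies — so uptake is conventionally
compared through coarse anatomical regions, losing voxel-level detail.
`spectreg` aligns the scans instead: an affine registration between a
subject's timepoints, and affine plus cubic B-spline free-form registration
between subjects, so that normalized uptake can be subtracted voxel by voxel
and averaged over a cohort.

Because each scan's CT and SPECT share one patient frame, every transform is
estimated on CT and applied verbatim to the SPECT. The pull-back convention
is used throughout: a transform maps fixed-image coordinates into the moving
image, so the moving image is resampled onto the fixed grid; the
inter-subject and intra-subject transforms concatenate as
`compose(inter, intra)` (reference space → subject post-operative space →
subject pre-operative space).

## Pipeline

1. **Preprocessing.** All volumes are resampled to a common
   0.98 × 0.98 × 3 mm grid; right legs are reflected about the plane through
   the CT grid centre perpendicular to the medio-lateral axis so every scan
   has left laterality (the reflection uses the CT grid centre for both
   modalities so their shared frame is preserved; any residual offset is
   absorbed by the registration). Three cuboidal volumes of interest (VOIs)
   — femur, tibia, patella — are built as the bounding boxes of their
   landmark subsets expanded by a 20 mm margin per side — the simplest
   auditable cuboid rule; both choices are configurable. An HU threshold
   isolates bone (default 200 HU) and masks the prosthesis (default
   2500 HU, dilated by 2 in-plane voxels and 1 slice to swallow residual
   metal streaks). The fibula head is part of the default femoral landmark
   subset, although it is anatomically a tibia-side structure; the subset
   is overridable.

2. **Registration.** Intra-subject: affine only, post-operative scan fixed,
   prosthesis masked out. Inter-subject: affine then B-spline, no
   prosthesis masking (all subjects carry the same implant). The tuned
   defaults are: smoothing-only anisotropic Gaussian pyramid (3 affine
   stages with factors 442, 221, 111; 4 non-rigid stages with 884, 442,
   221, 111; per-axis sigma = factor/2 voxels — the factors are read as
   blur levels, not downsampling ratios, since the pyramid is explicitly a
   smoothing pyramid), normalized mutual information with 16 bins for the
   affine stage and plain mutual information with 32 bins for the
   non-rigid stage, 2000 sample points per iteration, at most 2000 (affine)
   / 500 (non-rigid) iterations — the iteration budget is the only stopping
   rule — nearest-neighbour (affine) / linear (non-rigid) interpolation
   during optimization, and linear / cubic-B-spline final resampling. The
   B-spline control grid starts at (32, 32, 16) voxels × the stage
   multipliers (8,8,4), (4,4,2), (2,2,1), (1,1,1); each finer stage is
   warm-started by evaluating the coarser displacement at the new knots.

3. **SPECT analysis.** Each SPECT volume (carried on the resampled CT grid)
   is divided by its mean uptake inside a 35 × 20 × 3-voxel (2100-voxel)
   box centred in-plane on the femoral knee centre (FKC) and starting
   10 cm distally along +z — a shaft reference region that normalizes
   subject-specific tracer metabolization. The box is specified by its
   voxel count, the quantity actually used computationally; its physical
   volume follows from the grid spacing (6050.5 mm³ at the common
   0.98 × 0.98 × 3 mm grid) and is logged rather than prescribed. Differences (post − pre, both normalized) are computed on the
   post-operative VOI grid, carried into reference space through the
   inter-subject transform, and averaged voxel-wise with per-voxel subject
   counts; a per-voxel standard-deviation companion volume is written as an
   extension beyond the plain mean.

4. **Validation.** Dice similarity coefficient (DSC) of the bone masks with
   the ≥ 80 % success criterion; per-axis landmark index differences with
   the (2; 2; 0)-voxel criterion (nearest-integer rounding, half away from
   zero — the criterion is integral per case even though averages are
   reported fractionally); Wilcoxon signed-rank test of pre- vs
   post-registration DSC and a Mann–Whitney U test for the CT-resolution
   effect, both delegated to `stats::wilcox.test` and unit-tested against
   exact enumerations; a Kolmogorov–Smirnov normality check is reported
   alongside.

## The metric and its stochastic gradient

The joint histogram is built from sampled points with first-order (linear)
Parzen assignment to neighbouring bins, making the metric differentiable in
the moving intensity. Intensity ranges are fixed per pyramid stage from the
1–99 percentile of the masked fixed image and the full moving image, which
keeps metal streaks from stretching the binning. From the joint matrix,
`MI = H(F) + H(M) − H(F,M)` and `NMI = (H(F)+H(M))/H(F,M)` (entropies in
bits, `0·log 0 := 0`). The analytic gradient chains
d(metric)/d(histogram cell) → d(cell)/d(moving intensity) → trilinear
intensity gradient → d(point)/d(parameters); it is verified against central
finite differences in the test suite. Nearest-neighbour interpolation, used
for the affine metric *value* as configured, has a piecewise-constant — hence
derivative-free — intensity model, so the *derivative* always uses the
linearly interpolated model; this is the package's derivative model for the
sampled metric.

Sample points are drawn from the Halton sequence (bases 2, 3, 5) mapped to
the fixed-mask bounding box with a per-iteration random offset derived from
`(seed, iteration)`, rejecting points outside the mask; masks smaller than
ten times the sample count fall back to seeded with-replacement draws of
jittered voxel centres (a warning is emitted once per registration). Every
stochastic draw is seeded, so identical configuration and seed reproduce
bitwise-identical transforms.

## Optimization

The optimizer is Robbins–Monro stochastic gradient descent with gain
`γ(k) = a / (A + k)^α`, `A = 50`, `α = 0.602`, stopping exactly at the
iteration budget. Two numerical choices matter and were made deliberately:

* **Gain calibration.** `a` is auto-scaled from probe gradients so that the
  first iteration displaces the image by a configurable fraction
  (default 0.2) of an in-plane voxel, measured as the true displacement the
  step induces at the VOI corners. A single stochastic gradient's magnitude
  is dominated by sampling noise rather than drift, and `Σγ(k)²` over a
  2000-iteration budget is large: full-voxel noisy steps would random-walk
  the pose by many millimetres on the nearly flat early pyramid stages,
  while fraction-of-a-voxel steps keep that diffusion sub-voxel and still
  integrate tens of millimetres of systematic drift. Affine parameters are
  optimized in a scaled space (matrix entries scaled by the VOI radius) so
  a unit step means roughly 1 mm of displacement for every parameter.

* **Iterate averaging.** The returned parameters are the Polyak–Ruppert
  average of the final half of the iterates, which removes the residual
  random-walk jitter of the last stochastic steps; the unaveraged final
  iterate is also available from `asgd_minimize()`.

* **Initialization.** The affine stage starts from a moments match rather
  than plain centre-of-mass translation: centroids, the long-axis
  direction, the longitudinal scale and an isotropic transverse scale are
  taken from the second moments of the fixed bone mask and the thresholded
  moving image. Long bones are nearly axisymmetric, so the transverse
  eigenvectors are degenerate and the rotation about the long axis is
  unidentifiable from moments; that last degree of freedom is resolved by a
  coarse exhaustive search (±12° in 2° steps) over the smoothed NMI — the
  standard remedy when the expected misalignment exceeds a gradient
  optimizer's capture range. Implausible moment matches (scales outside
  [0.75, 1.35] or rotations beyond 35°) fall back to the centre-of-mass
  translation.

## The phantom generator

Clinical knee SPECT/CT cannot be redistributed, so the package generates
synthetic paired scans with exact ground truth. The default phantom mimics
the clinical data regime: CT at 0.98 × 0.98 × 3 mm (a 1.27 × 1.27 × 3 mm
option exists for resolution-effect experiments) on a reduced
160 × 160 × 80 grid (~157 × 157 × 240 mm — enough to hold the knee and the
10 cm normalization offset at desk-scale runtimes), SPECT at 4.79 mm
isotropic over the same extent. Bones are cylinders with cortical shells
and ellipsoidal condyles/plateau/patella over a soft-tissue cylinder
(HU: soft 40, trabecular 300, cortical 1100, implant 3000); the
post-operative scan adds a metal slab in the medial tibial plateau.
Gaussian CT noise (sd 15 HU) and Poisson-like multiplicative SPECT noise
(sd = 0.5·√counts) are seeded and explicit. Trabecular and soft-tissue
heterogeneity is emulated by a smooth anatomy-locked random field (sums of
long-wavelength cosines, 30–80 mm, sd 80 HU in bone and 30 HU in soft
tissue): it is tissue, not noise, so both timepoints of a subject share it
and it deforms with the anatomy. Uptake hotspots are Gaussian blobs
confined to bone (the tracer binds to remodelling bone); the default
post-operative-only hotspot sits below the tibial insert in the
posterolateral position. Cohorts add per-subject anthropometric affine
variation (±10 % per-axis scaling, small shear) and a seeded rigid
misalignment of the pre-operative scan.

What the phantom does *not* emulate: CT beam-hardening/streak artefacts
(only their masking is exercised), realistic SPECT projection/reconstruction
physics, partial-volume effects at air/tissue boundaries, and true
trabecular micro-architecture. Passing the recovery experiments therefore
demonstrates that the registration machinery recovers known misalignments
under realistic intensity statistics and noise — not that clinical accuracy
equals the phantom accuracy.

## Problem sizes and verification

The recovery experiment registers ten seeded phantom pairs (rotation ≤ 10°,
translation ≤ 15 mm, per-axis scaling ≤ 8 %) at the full tuned
configuration and checks the platform's validation criteria: femoral
bone-mask
DSC ≥ 80 %, landmark differences ≤ (2; 2; 0) voxels, and a significant
signed-rank improvement of DSC. `scripts/acceptance.R` runs it on the
default 160 × 160 × 80 phantom grid; the in-suite copy uses the same knee
at 128 × 128 × 80 (1.22 × 1.22 × 3 mm) so the whole battery fits one test
run. The cohort experiment runs five subjects end to end (intra, inter,
normalization, difference, aggregate) at 112 × 112 × 80
(1.4 × 1.4 × 3 mm) and requires the injected post-operative hotspot to
reappear in the aggregate map within two SPECT voxels of its true
location. Unit tests run reduced iteration budgets; all full-configuration
checks live in the acceptance suite and in `scripts/acceptance.R`.

## Known limitations

* NIfTI-1 is the supported interchange format; DICOM series must be
  converted upstream.
* Only axis-aligned acquisitions are accepted (non-identity direction
  cosines are rejected at read time).
* The affine capture range relies on the moments initializer; grossly
  pathological bone masks (e.g. near-empty thresholded volumes) fall back
  to centre-of-mass translation and may need a manual pre-alignment.
* Aggregate maps carry no voxel-wise hypothesis testing; the
  standard-deviation companion is descriptive only.
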
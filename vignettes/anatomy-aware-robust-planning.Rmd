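---
title: "Anatomy-aware robust proton planning at phantom scale: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy-aware robust proton planning at phantom scale: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`anatrobust` studies a question from adaptive head-and-neck proton therapy:
when image guidance reduces the day-to-day setup error to about 1 mm, can the
conventional 3 mm robustness margin (cRO3mm) be replaced by the true 1 mm
margin plus an explicit model of how the patient's anatomy will change over
the treatment course (aRO1mm), without losing target coverage — and with how
much sparing of the salivary and swallowing structures?  The package builds
the whole chain needed to ask that question on synthetic patients: a
longitudinal digital phantom, a population average-deformation model, an
analytic proton pencil-beam dose engine, a minimax robust spot-weight
optimizer, deformable dose accumulation over a simulated 35-fraction course,
and the evaluation layer (worst-case DVH metrics, logistic NTCP models,
gamma analysis, paired Wilcoxon comparisons).

## The synthetic cohort

Each patient is an idealized axial head-and-neck anatomy on a shared template
grid (default 64 x 64 x 48 voxels at 3 mm, world coordinates in mm, three
tissue classes: air 0.001, water 1.0, bone 1.5 relative stopping power).
Structures are analytic solids: a high-risk CTV sphere slightly left of
midline, an elective/nodal collar around the neck axis that spares an
anterior wedge and a notch around the spinal canal, bilateral parotid and
submandibular glands, three pharyngeal-constrictor slabs, oral cavity,
brainstem, spinal cord inside a vertebral-bone annulus, and a thyroid (the
thyroid is generated for completeness of the emulated population statistics
but carries no planning goal downstream).

Progressive interfractional change is generated by an analytic **forward**
displacement field (planning frame to week *w*, weeks at fractions 5, 10,
..., 30):

* per-organ isotropic contraction about the organ centroid, scaled so a loss
  fraction *f* at week 6 shrinks the organ by exactly `(1-f)^(1/3)` per axis.
  The support weight is 1 out to 1.3x the organ radius and decays smoothly
  beyond, so the contraction is exact over the entire organ — a voxel-counted
  volume ratio then reproduces the requested loss within voxelization noise.
  Large target fields use a tighter support so they do not reach into the
  glands;
* a medial drift of the parotids (and a small fixed 0.3 mm one for the
  submandibular glands), linear in time;
* a cross-sectional contraction of the elective collar about its mid-circle,
  blending the nodal rate anteriorly into the elective rate posteriorly;
* an inward "neck contraction" of the body outline, strongest inferiorly;
* a random smooth perturbation field (sNRV), drawn fresh each week on a
  coarse lattice, upsampled, and scaled to a requested RMS amplitude.

Weekly images and contours are voxelized through the numerically inverted
field (fixed-point iteration; the forward/backward composition residual is
well under a quarter voxel at the 99th percentile).  Target volume rates are
interpreted as linear fraction-of-initial-volume per treatment day, capped at
90%; gland losses are totals reached at week 6.

Default progression parameters are the emulated population means: CTV losses
1.5 / 2.3 / 0.3 % per day (primary / nodal / elective), parotid loss
28.6 +/- 14.6 % with a 2.3 mm medial shift, submandibular 26.6 +/- 17.1 %,
thyroid 12.3 +/- 11.3 %, and a 3 +/- 1 mm neck contraction with 1 mm sNRV —
the latter two chosen so the mean 3D displacement of the CTVs lands in the
2.5-3.7 mm range of the emulated cohort.  Cohort draws are truncated normals
with child seeds derived deterministically from one master seed.

What the generator does **not** emulate: CT texture and heterogeneity beyond
three tissue classes, intrafraction/respiratory motion, systematic
setup-posture changes (e.g. shoulder drop), registration error in the
accumulation step (ground-truth fields are used), and baseline anatomical
variation between patients — all patients share the template planning
anatomy, which is the stated stand-in for registration-based inter-patient
correspondence.  Passing tests therefore demonstrate the machinery and the
direction of the strategy comparison under controlled conditions, not
clinical magnitudes.

## The average model

The model is the voxelwise arithmetic mean of the training patients' forward
weekly fields — identity correspondence makes this exact on the template.
Prediction warps the planning image by the inverted mean field; organ-at-risk
and low-risk CTV contours are propagated by nearest-neighbour sampling, while
the high-risk CTV keeps the planning contour (the contour rule used in the
adaptive strategy).  Leave-one-out validation reports symmetric mean surface
distance (boundary voxels by 6-connectivity erosion) of predicted vs. true
weekly contours against the no-model baseline.

## Dose engine

An analytic pencil-beam model chosen for desk-scale speed:

* normalized depth-dose = logistic plateau shoulder (height 0.3, width 2 mm)
  plus a Gaussian Bragg peak (sigma 4.5 mm, constant with range); the curve
  is calibrated numerically so the requested R80 is the distal
  80%-of-maximum depth;
* single lateral Gaussian with sigma(z) = sigma0 + 0.02 z (sigma0 = 6 mm at
  the surface), cut off at 2.5 sigma; no nuclear halo;
* water-equivalent depth from beam-aligned WEPL volumes (ray marching at
  2 mm steps on a 3 mm lateral lattice, trilinearly resampled);
* setup error = rigid translation of the evaluation frame; range error =
  division of WEPL by the range-scale factor;
* six coplanar beams (gantry 45, 315, 90, 270, 160, 200 degrees); spots on a
  10 mm lateral lattice with 10 mm energy-layer spacing covering the
  quantized target depths of every planning/predicted anatomy, padded one
  cell laterally (8-neighbourhood) and one layer in depth for the scenario
  margins.

Lattice spacing, sigma and the curve shape are configuration, pinned by
their own 1D oracles in the tests.

## Robust optimization

Scenario sets follow the 14-direction convention (6 face + 8 corner
directions scaled to the setup magnitude) crossed with the two pure range
errors; per anatomy that is 28 error scenarios, so the adaptive strategy
(planning + predicted weeks 1, 3, 5) optimizes over 112, while the
conventional strategies use 28 on the planning anatomy.  The nominal
scenario enters the objective as a separately weighted term (lambda = 1)
rather than inside the max — whether the clinical system includes it in the
max is unstated, and the separate term keeps the nominal plan quality
observable.

The composite objective is a sum of volume-normalized one-sided quadratic
terms: dual-level CTV minimum-dose terms (a heavily weighted tail term at
95% of prescription and a shaping term at prescription), CTV maximum-dose
terms at 103%/110%, brainstem/cord maximum terms at 54/45 Gy, and linear
mean-dose terms for the parallel organs (nominal scenario only).  The
minimax is smoothed by a log-sum-exp with annealed temperature and minimized
by projected L-BFGS-B under the nonnegativity bound, warm-started from a
nominal-only fit.  Two numerical devices keep the inner loop fast: all
per-scenario influence matrices are stacked into one sparse operator
(evaluated by dedicated triplet kernels), and influence entries below 0.04
are truncated with each row rescaled by its exact/truncated dose ratio at
uniform weights, so the optimizer sees unbiased dose totals.  Structure
voxels are subsampled for optimization with all-surface emphasis (surface
voxels carry the setup-shift coverage penalties); evaluation uses a denser,
strided sample.  The worst-case trace reported after each annealing round
retains the best iterate and is nonincreasing by construction.

Because every synthetic patient shares the template planning anatomy, the
conventional plans are patient-independent and the study pipeline computes
them once (with a doubled iteration budget); the adaptive plan is recomputed
per patient from its leave-one-out model.

## Course simulation and accumulation

Each weekly anatomy is first rigidly aligned to the planning image
(translation-only least-squares on body voxels, emulating image-guided
setup).  The 28 residual scenarios (1 mm, +/-3%) are recomputed per week;
voxel-wise minimum/maximum and the nominal dose are read at the planning
structure voxels mapped through the ground-truth forward field (no
registration error, the stated stand-in for deformable registration), and
accumulated with fraction weights 5,5,5,5,5,10 over weeks 1-6 — the mapping
of 35 fractions onto six weekly anatomies is not dictated by the emulated
protocol, so fractions 31-35 reuse the week-6 anatomy; the weights are
configurable.  Accumulating voxmin with voxmin (and voxmax with voxmax) is
deliberately conservative and mirrors the evaluation convention of the
emulated study.  For speed, the error scenarios are evaluated only at target
and serial-organ voxels (whose metrics read the worst-case channels);
parallel organs are evaluated on the accumulated nominal dose, which is the
only channel their metrics use.

## Evaluation

V94 is the percent of structure volume at or above 94% of prescription,
evaluated on the accumulated voxmin channel for the CTVs; D2% and D0.03cc
interpolate the cumulative sorted-volume curve; serial organs are checked on
accumulated voxmax (and nominal) against the clinical limits (brainstem
68/63.1 Gy, cord 58.5/55 Gy, optic structures 64/59.5 Gy when present — the
phantom omits optic structures, whose goals then report NA and are skipped);
a replanning flag is raised when accumulated CTV V94(voxmin) falls below
94%.  NTCP uses the two printed logistic models — xerostomia from the
submandibular mean dose and square-root parotid mean doses, dysphagia from
oral-cavity and constrictor mean doses with a pharynx-site flag (TRUE for
this nasopharynx-like phantom) — applied to physical accumulated mean doses
without fractionation correction.  The paired Wilcoxon test wraps the exact
signed-rank distribution (zero-drop convention) for small samples.

## Problem sizes and runtime choices

The shipped defaults are the sizes the package's own study runs at: 64 x 64
x 48 voxels at 3 mm, a 20-patient cohort with 10 validation patients,
roughly 3,000-3,500 spots per plan, 350 surface + 150 interior optimization
voxels per target structure, 100 L-BFGS-B iterations per annealing round
(doubled for the once-per-study conventional plans), and up to 2,500
evaluation voxels per structure.  The model-recovery analyses in the test
suite run on a 48 x 48 x 36 grid at 4 mm — the convergence property being
tested is resolution-independent.

## Known limitations

Fixed axial gantry angles (no couch rotation or beam-specific hardware), a
single-Gaussian lateral model without halo, constant Bragg-peak width with
range, dose (not energy) interpolation during warping, conservative
worst-case accumulation, template-identical baseline anatomy across
patients, and an objective configuration that was commissioned on the
default phantom rather than matched to any clinical system.  Magnitudes of
the strategy differences reported on this phantom are therefore illustrative;
the package asserts directions, not clinical effect sizes.
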
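---
title: "Closed-loop fetal brain tracking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop fetal brain tracking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Functional fetal MRI — BOLD imaging, T2\* relaxometry, diffusion — acquires
the same EPI slice stack many times over minutes. Fetal motion is large,
unpredictable and cannot be restrained, so repetitions drift apart and
quantification suffers in ways retrospective registration cannot fully
repair. Prospective motion correction tackles this at the source: the
scanner's field of view (FOV) is recentered on the fetal head *during* the
scan, using the target images themselves as intrinsic navigators.

`fetaltrack` implements this closed loop at desk scale, end to end and fully
testable, with a simulated scanner in place of the real one:

1. **Acquire** one EPI-like 3D repetition of an analytic scene at the
   controller's current FOV.
2. **Localize** the target — an intensity-based segmenter (the phantom
   path) or a 3D UNet trained with the generalized Dice loss.
3. **Track**: take the mask's center of mass (CoM) in world coordinates
   and report its displacement between repetitions *n* and *n − 2*.
4. **Correct**: queue a FOV-recentering update that takes effect with a
   two-repetition latency, mirroring the deployed system's timing.

Everything downstream — Dice/IoU of the localization, per-axis CoM MSE,
latency tables, recentering residuals — is computed by the evaluation
module and returned as tibbles.

## Coordinate conventions

World coordinates are millimetres on a fixed x/y/z frame (right→left,
bottom→top, front→back of the bore). A `grid_geometry` ties a voxel grid to
that frame through its isotropic spacing and the world position of the
*continuous grid midpoint* `(shape + 1) / 2` (1-based indexing), which is
the FOV center by construction. This choice makes `voxel_to_world()` and
`world_to_voxel()` exact inverses and keeps even-sized grids symmetric at
the cost of a half-voxel-offset center — the property the whole feedback
arithmetic rests on. NIfTI files are written with a diagonal affine that
encodes exactly this convention; it had to be frozen for bit-exact I/O
round trips, since there is no single canonical NIfTI affine convention.

Preprocessing for the network maps any stack to a fixed 128³ grid
(`pad_crop_to_grid()`): centered zero-padding and/or cropping, with the
output geometry's FOV center adjusted so that retained voxels keep their
world coordinates. Anisotropic inputs are first resampled to the smallest
voxel spacing (trilinear for images, nearest-neighbour for masks); whether
such resampling should preserve physical FOV or voxel counts is genuinely
ambiguous, and this package fixes one consistent reading: resample to
isotropic spacing, then pad/crop to the target grid.

## The acquisition model

Image formation is deliberately minimal: analytic components (spheres,
ellipsoids, boxes) are rasterized at voxel centers, each voxel takes the
mono-exponential gradient-echo signal `S = S0 · exp(−TE / T2*)` of the
component occupying it (later components overwrite earlier ones), and
seeded Gaussian noise is added in the image domain. No k-space model, EPI
distortion or ghosting is simulated — the tracking loop consumes magnitude
images, and its correction does not model those artifacts either. Motion
is instantaneous between repetitions (single-shot acquisitions freeze
intra-volume motion) and purely translational; rotation correction is out
of scope and a real limitation of the approach.

Defaults mirror the phantom protocol the loop is evaluated on: 3.0 mm
isotropic voxels, TE 90 ms, 50 repetitions, on a 64³ grid (192 mm FOV).
The sphere phantom (radius 45 mm, T2\* 60 ms against a dark background)
stands in for an agarose phantom with brain-like relaxation; T2\* values
are fixture choices, not measured values. The fetal scene adds an
ellipsoidal "head" (half-axes ~25–34 mm, T2\* 60 ms), a dim uniform
maternal background (S0 20, T2\* 30 ms), and a confounding high-signal
blob (radius 10–16 mm, T2\* 80 ms) standing in for the maternal stomach —
the structure that intensity-driven segmentation demonstrably latches
onto. Step displacements default to multiples of the 3 mm voxel so that
recentering is numerically unambiguous; published phantom work does not
report its displacement magnitudes.

Noise streams are seeded per repetition (`seed + repetition`), so each
frame is independent yet the whole series is a deterministic function of
one seed.

## The localizer

### Generalized Dice loss

The network trains by minimizing the generalized Dice loss over M classes,

$$L = 1 - 2\,\frac{\sum_k w_k \sum_n p_{kn} t_{kn}}
                 {\sum_k w_k \sum_n (p_{kn} + t_{kn})},
\qquad w_k = \frac{1}{(\sum_n t_{kn})^2},$$

with per-voxel predicted probabilities \(p\) and one-hot targets \(t\).
The inverse-squared-volume weights balance a small brain against a vast
background. When a class is absent the weight diverges and the loss is
undefined; this implementation skips absent classes (weight 0), the
common practice, keeping the loss finite and in \([0, 1]\] with equality
to zero exactly at a perfect one-hot prediction. The implementation is
verified against an independent brute-force double loop over classes and
voxels to 1e-10.

### Architecture

The localizer is a five-level 3D UNet: per encoder stage two repeated
blocks of 3×3×3 convolution (stride 1), instance normalization and
LeakyReLU; 2×2×2 average pooling for the first two downsamplings and
2×2×2 max pooling for the remaining two; a mirrored decoder with
channel-concatenation skips; and a final 1×1×1 convolution to two output
classes (background, target). The reference configuration uses channels
(32, 64, 128, 256, 512) on a 128³ input. Published descriptions leave the
decoder's upsampling operator, the learning rate, epochs, batch size and
augmentation parameters unstated; here the decoder upsamples trilinearly
followed by a 3×3×3 convolution (the standard UNet form), and all training
hyperparameters are explicit `train_config()` fields rather than guessed
"reference values". Binarization is per-voxel argmax with exact ties going
to background — with two classes a probability threshold would add a free
parameter the system does not need.

The network, its backward pass and Adam (β₁ = 0.9, β₂ = 0.999, the
conventional defaults) are implemented natively: convolutions via im2col
feeding BLAS matrix products in single precision (the operation is memory
-bandwidth bound; weight updates re-accumulate in double precision), with
gradients verified against central finite differences. Instance
normalization carries no affine parameters, matching the common default —
a convolution bias followed by instance norm is a no-op, which the
gradient check makes visible.

### Desk-scale profiles and the training experiment

Three same-family profiles are shipped: `full` (32…512 channels, 128³),
`small` (16…256, 64³) and `tiny` (4…64, 64³). Architecture-fidelity
checks introspect `full`; the shipped training experiments use `tiny`,
whose capacity is ample for the synthetic task while keeping a full
training run on a single CPU in minutes. The parameter-recovery
experiment trains `tiny` on 32 synthetic head scenes (held-out 6) at 64³,
three epochs of Adam at learning rate 1e-2, batch size 1 — chosen from
pilot convergence curves on this task (held-out Dice typically crosses
0.9 during the third epoch and the loss is still descending when training
stops, so these are floor settings, not tuned optima). Held-out mean
Dice ≥ 0.90 across seeds is the acceptance bar.

What passing this shows — and what it does not: the synthetic scenes have
sharp boundaries, stationary contrast, spatially white noise and a single
confounder geometry. Real EPI data add B0 distortion, ghosting, coil
shading, maternal anatomy and through-plane motion; a model trained here
says nothing about clinical Dice levels. The experiment validates the
*training machinery* (loss, gradients, optimizer, data plumbing), which
is exactly what a synthetic harness can validate.

## The controller

The tracked quantity is the CoM of the predicted mask, mapped to world
coordinates under the acquiring repetition's own geometry — so a static
object has an invariant world CoM no matter how the FOV moves. Records
report the displacement between repetitions *n* and *n − 2* (the deployed
system's feedback signal), but the FOV is driven by a *pending-aware
recentering correction*: `(CoM − FOV center) − (queued, not-yet-applied
shifts)`, clipped per axis. The distinction matters: a step displacement
remains visible in the two frames before its correction lands, so feeding
back the raw n/n−2 displacement every repetition would double-correct and
oscillate. How the deployed system avoids this is not described; the
pending-shift ledger is this package's solution, chosen because it
reproduces the observable single-shift-per-event behavior and is
provably stable.

Corrections computed from repetition *n* take effect at *n +
latency_repetitions* (default 2, configurable — the latency is an
implementation property, not a law). The plausibility gate suppresses
corrections from masks whose volume leaves configurable bounds
(default 10–1000 ml, covering both the ~65 ml synthetic head and the
~382 ml phantom sphere), and `max_shift_mm` (default: half the FOV
extent) bounds any single update so a catastrophic mis-segmentation
cannot throw the FOV off the scene. A half-voxel update deadband
(`min_update_mm`) suppresses corrections below the grid's resolving
power, so sub-voxel rasterization or noise residuals left after a
correction cannot retrigger updates indefinitely. An empty or failed
localization holds the last FOV — the safest scanner-side behavior. All
these guards are this package's choices where the deployed system is
silent; all are config-disable-able.

Numerical edge cases are pinned down explicitly: warm-up (n < 3) yields
no displacement estimate; an empty mask is a missing observation, never
an error; ties in the argmax binarization go to background; two
corrections queued for the same repetition sum.

## Evaluation

Dice and IoU are computed per mask pair, with both-empty defined as 1 and
one-empty as 0 (avoiding 0/0 by the convention that agreement on
"nothing there" is perfect agreement). For binary masks IoU =
DSC/(2 − DSC) exactly, which the tests exploit as an identity check. CoM
trajectory error is reported per axis as both MSE (mm²) and RMSE (mm),
because published "MSE in mm" tables are dimensionally ambiguous —
reporting both sidesteps the question. Grouped summaries (`by` echo time,
gestational-age class, presentation, …) return mean ± sd per group; no
hypothesis testing is attached because none is meaningful at these group
sizes.

The phantom experiment (`run_phantom_experiment()`) is the package's
acceptance surface: a noise-free sphere-phantom run with step
translations timed so corrections land at repetitions 9, 20, 31, 38 and
48; it checks exact two-repetition latency, exactly one shift per event,
and image-frame CoM agreement with repetition 1 within one voxel at every
corrected repetition.

## Problem sizes

The shipped experiments run on 64³ grids with 50-repetition series and a
`tiny`-profile network — sizes chosen so that the full suite, including
three training runs, completes on a single CPU in well under half an
hour while exercising every code path at the fidelity the claims need.
The 128³ `full` profile is instantiated and shape-checked but not
trained; training it is a GPU-scale undertaking orthogonal to what the
synthetic harness validates.

## Known limitations

- Translations only; rotations are neither simulated nor corrected.
- No k-space, distortion, ghosting, coil-sensitivity or breathing model.
- The synthetic confounder is a single blob; real mis-segmentation
  geometry is richer.
- Clinical Dice levels are not reproducible from this package; they
  require the clinical training data and trained weights.
- The two-repetition latency is modeled as exact; a real pipeline's
  latency jitters with reconstruction load.
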
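# fetaltrack

Closed-loop fetal brain tracking and prospective field-of-view (FOV)
correction for dynamic MRI, implemented as a desk-scale, fully testable R
package.

## The problem

Functional fetal MRI (BOLD, T2\* relaxometry, diffusion) acquires the same
EPI volume many times over minutes, and fetal motion — large, unpredictable,
unrestrainable — corrupts exactly the repeated structure these techniques
rely on. Prospective motion correction recenters the scanner's FOV on the
fetal head *during* the scan, using the target images themselves as
intrinsic navigators: each repetition is segmented in real time, the brain's
center of mass (CoM) is tracked, and the displacement between repetitions
*n* and *n − 2* drives a FOV update that lands two repetitions after the
motion appeared.

`fetaltrack` re-implements that loop end to end against a simulated scanner,
for researchers who want to study, test or extend the controller without a
scanner in the room:

- **Simulated acquisition** of EPI-like dynamic volumes: analytic scenes
  (sphere phantom, fetal-head ellipsoid with a confounding "stomach" blob),
  mono-exponential T2\* contrast `S = S0 · exp(−TE/T2*)`, step-translation
  motion, seeded Gaussian noise.
- **Two localizers**: Otsu-threshold + largest-component intensity
  segmentation (the phantom path), and a natively implemented five-level 3D
  U-Net (channels 32–512, instance norm, LeakyReLU, average-then-max
  pooling, 2 output classes) trained with the generalized Dice loss

  L = 1 − 2·(Σₖ wₖ Σₙ pₖₙ tₖₙ)/(Σₖ wₖ Σₙ (pₖₙ + tₖₙ)),  wₖ = 1/(Σₙ tₖₙ)²

  under Adam (β₁ = 0.9, β₂ = 0.999) — convolutions, backward pass and
  optimizer built on Rcpp/BLAS, gradient-checked against finite differences.
- **The controller**: per-repetition CoM in world coordinates, n vs n−2
  displacement reporting, pending-aware recentering corrections with
  configurable latency (default 2 repetitions), a mask-volume plausibility
  gate and per-update clipping.
- **Evaluation**: Dice, IoU (= DSC/(2−DSC) for binary masks), per-axis CoM
  MSE, grouped mean ± sd summaries, and a phantom experiment report with
  latency tables and recentering residuals.

Audit trails, metric records and training histories are tibbles; fitted
objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

A 50-repetition noise-free phantom run in which the sphere jumps +9 mm in x
so that the displaced phantom first appears in the image of repetition 7:

```r
library(fetaltrack)

cfg <- phantom_config(n_repetitions = 50, edge = 64, noise_sigma = 0,
                      events = list(motion_event(7, c(9, 0, 0))))
report <- run_phantom_experiment(cfg)
report
#> <phantom_report>
#> # A tibble: 1 × 3
#>   event_rep correction_rep latency
#>       <int>          <int>   <int>
#> 1         7              9       2
#> max |residual| at corrected repetitions: 0.000 voxel
#>   all_events_corrected         pass
#>   latency_exact                pass
#>   one_shift_per_event          pass
#>   residuals_within_one_voxel   pass
#>   loop_completed               pass
```

Reading the output: the step is visible from repetition 7; the controller
computes a +9 mm correction from that image and, with the loop's
two-repetition latency, the FOV center changes at repetition 9 — after
which the phantom's image-frame CoM matches repetition 1 to within a voxel
and no further shifts fire (no oscillation). `tidy(report$records)` exposes
the full per-repetition audit trail (FOV centers, CoMs, displacements,
shifts, flags); `autoplot(report$records)` draws the CoM/FOV traces.

Training the reduced U-Net on synthetic fetal-head scenes:

```r
ds  <- synth_head_dataset(38, edge = 64, seed = 1000)
fit <- train_localizer(ds[1:32], ds[33:38],
                       train_config(epochs = 3, learning_rate = 1e-2, seed = 0))
tail(tidy(fit), 1)
#> # A tibble: 1 × 3
#>   epoch train_gdl val_dsc
#>   <int>     <dbl>   <dbl>
#> 1     3     0.404   0.973
```

i.e. after three epochs (a few minutes on one CPU) the held-out mean Dice
against the analytic head masks is ≈ 0.97.

There is also a thin CLI over the same functions
(`inst/cli/fetaltrack simulate|train|track|evaluate --config cfg.yaml
[--seed N] [--out DIR]`), which writes a self-describing run directory
(config snapshot, manifest with seed and input hashes, logs, outputs).

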
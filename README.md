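# spindletrack

Automated detection, model-based fitting, and tracking of fluorescently
labeled microtubules and mitotic spindles in 3D live-cell image stacks,
written for the kind of data produced by spinning-disk confocal imaging of
yeast: anisotropic voxels (~0.1 µm in XY, ~0.5 µm in Z), low photon
budgets, and microtubules organized by spindle-pole bodies into monopolar,
bipolar, or astral geometries.

Who it is for: cell biologists and image analysts who need *quantitative*
microtubule measurements — bundle counts, lengths, lifetimes,
polymerization/depolymerization speeds — from 3D time-lapse movies, without
hand tracking.

## The model

Every image is represented as a uniform background plus a sum of parametric
Gaussian intensity features, fit directly to the voxel data:

- **Spot** (pole / SPB): `f(x) = A exp(-Σ_a ((x_a - c_a)/σ_a)²)` — 7
  parameters (amplitude, center, per-axis widths).
- **Line** (straight microtubule or bundle): the integral of point
  Gaussians along a straight centerline over normalized arc length
  `t ∈ [0,1]` — 10 parameters; evaluated in closed form with error
  functions.
- **Curve** (bent astral microtubule): a start point, unit initial tangent
  (2 angles), and a Fourier curvature model
  `K(t) = k0 + Σ_i p_i cos(iwt) + q_i sin(iwt)` (N = 2) — 15 parameters;
  the centerline is reconstructed by tangent stepping and the intensity
  integrated by Gauss quadrature.

Per frame, the pipeline is: geometric detection on the maximum-intensity
projection (pole finding by Otsu + extended-maxima H-transform, angular
scanning for lines, ridge tracing for curves) → bounded Levenberg-Marquardt
least squares, locally per feature and then globally including the
background → feature-count selection by nested-model f-tests (add
candidates proposed from the residual image; prune insignificant features).
Frames are then linked in time by linear-assignment tracking with gap
closing, and short-lived features are discarded as spurious. A calibrated
simulator generates synthetic stacks with ground truth for benchmarking
the whole chain at controlled signal-to-noise ratio (SNR = mean
background-subtracted microtubule intensity over the image median).

See `vignettes/spindletrack-methods.Rmd` for the full account of the
models, algorithms, and numerical choices.

## Worked example

```r
library(spindletrack)

# simulate a monopolar spindle stack at SNR 2 and analyze it
sim <- simulate_image(simulation_config(target_snr = 2, seed = 3))
sim$truth
#> <ground_truth [monopolar]: 3 microtubules, SNR 2.09, seed 3>

fit <- fit_frame(sim$image, "monopolar")
report <- classify_detections(fit$model, sim$truth)
report
#> <detection_report: 3 true, 4 detected -> 3 correct, 1 spurious, 0 missed>

position_errors(report, c(0.1, 0.1, 0.5))$summary
#>      metric       mean         se
#> 1 err_xy_um 0.03871568 0.01192981
#> 2  err_z_um 0.10574628 0.06269219
#> 3 err_xy_px 0.38715680 0.11929813
#> 4  err_z_px 0.21149257 0.12538437
#> 5 err_3d_px 0.69824187 0.12395783
```

All three simulated microtubules are recovered (one extra detection is
spurious) with tips localized to a fraction of a pixel — 0.04 µm in XY on
average here, i.e. a mean 3D pixel-normalized error of 0.70. For movies, use
`run_pipeline(run_config(...))`, which adds time linking and writes
per-frame fits (JSON), tracks (CSV) and a run summary; dynamic-instability
events are then extracted from track length series with
`detect_dynamic_events()`.

A thin command-line wrapper is installed at `inst/cli/spindletrack`
(subcommands `simulate`, `detect`, `fit`, `track`, `validate`,
`dynamics`).

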
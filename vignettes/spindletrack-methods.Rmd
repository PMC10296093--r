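---
title: "Models and methods behind spindletrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spindletrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spindletrack)
```

spindletrack detects, fits, and tracks fluorescently labeled microtubules
and mitotic spindles in 3D live-cell image stacks, with a simulator and a
validation harness for benchmarking the whole pipeline at controlled
signal-to-noise ratio (SNR). This vignette describes the underlying models,
the algorithmic and numerical choices, and what the synthetic benchmarks do
and do not demonstrate.

## Intensity models

Every feature is a parametric source of Gaussian fluorescence evaluated at
voxel centers in physical (micron) coordinates; voxel `(i, j, k)` (1-based)
is centered at `((i-0.5)dx, (j-0.5)dy, (k-0.5)dz)`. Placing coordinates at
voxel centers (rather than corners) avoids a half-voxel localization bias.
Typical voxels are anisotropic: 0.1 µm in XY and 0.5 µm in Z.

**Spot.** A point source (a spindle-pole body plus its unresolved short
microtubules) with peak amplitude `A`, center `x0` and widths `σ = (σx, σy,
σz)`:

    f(x) = A exp(-((x-x0)/σx)^2) exp(-((y-y0)/σy)^2) exp(-((z-z0)/σz)^2)

There is no normalization constant, so `A` is the peak intensity; 7 free
parameters.

**Line.** A straight microtubule or bundle is the integral of point
Gaussians along the centerline from `p0` to `p1`, parameterized by
normalized arc length `t ∈ [0, 1]`; 10 free parameters. Expanding the
exponent in `t` gives a Gaussian integral that reduces to error functions:
with `α = Σ u_a²/σ_a²`, `β = Σ d_a u_a/σ_a²`, `γ = Σ d_a²/σ_a²` (where `d =
x − p0`, `u = p1 − p0`),

    f(x) = A (√π / 2√α) exp(β²/α − γ) [erf(√α − β/√α) − erf(−β/√α)]

The closed form is exact and fast and is the default; a composite
Gauss-Legendre quadrature path is kept as an independent cross-check (the
two agree to better than 1e−6 of the peak on randomized lines, a property
the test suite asserts). A degenerate line with `p0 == p1` renders exactly
as a spot.

Note a consequence of the normalized-`t` parameterization: at fixed `A`, a
longer line spreads the same integrated weight over more voxels, so the
*peak* brightness of a line scales like `A√π σ/L`. The fitted amplitude
therefore absorbs the length; when an application needs "brightness per
unit length" semantics (as the simulator does), the amplitude must be
rescaled accordingly.

**Curve.** Bent microtubules (astral microtubules in budding yeast) use an
intrinsic-geometry model: a start point `x0` (3), an initial unit tangent
stored as azimuth/polar angles (2), a Fourier curvature model over
normalized arc length

    K(t) = k0 + Σ_{i=1..N} p_i cos(i w t) + q_i sin(i w t)

with `N = 2` by default (6 coefficients incl. `w`), and the widths (3): 15
free parameters. The centerline is reconstructed by explicit Euler
stepping:

    x(t+dt) = x(t) + dt T(t)
    T(t+dt) = T(t) + N(t) K(t) dt,   N = (−Ty, Tx, 0)

Two numerical choices matter here. First, the tangent is renormalized to
unit length after every step: the raw update inflates `|T|` at second order
in `dt`, and renormalization keeps `t` an arc-length parameter (without it
the reconstructed length drifts). Second, the rotation producing the normal
acts purely in the XY plane with a zero Z component. Curvature therefore
bends the curve only in XY and the Z component of the centerline stays
linear — matching how these curves are detected (in a Z projection) and
fit (degree-4 polynomial in XY, degree-1 in Z). The reconstruction is
first-order accurate; with `dt = L/2000` (the rendering default) the
endpoint error against an analytic circular arc is far below a nanometer.
Curve intensity is the same Gaussian line integral, evaluated by composite
Gauss-Legendre quadrature along the reconstructed centerline (default 32
nodes per panel, one panel per `2 min(σx, σy)` of arc, so the integrand is
smooth within each panel).

**Parameter counts.** The 15-parameter curve count requires the initial
tangent to be a *unit* vector (2 angles rather than 3 components); we adopt
that reading and assert the 7/10/15 packing programmatically. The arc
length `L` is carried as a separate shape parameter: detection initializes
it from the traced path, and the optimizer refines it as an additional
bounded parameter by default (`fit_curve_length`); both "fixed from
detection" and "optimized" modes are exposed because which of the two is
preferable depends on how trustworthy the trace is.

**Composite model.** An image model is a uniform background `B0` plus the
sum of all feature renders, organized by a topology tag (monopolar,
bipolar, astral, free) and an attachment map recording which line/curve
start points are anchored at which pole. Rendering is exactly additive and
order-independent.

## Detection

Detection produces initial guesses only; all quantitative claims rest on
the subsequent fit.

1. **Preprocessing.** A separable 3D Gaussian filter (defaults 1 voxel in
   XY, 0.5 in Z) suppresses voxel noise; the maximum-intensity projection
   (MIP) along Z gives the 2D working image. The background level is
   defined throughout as the *median intensity of the unfiltered image*.
2. **Pole finding.** Otsu thresholding of the MIP restricted by an
   extended-maxima H-transform (grayscale reconstruction with suppression
   height `h`, default 3x the robust noise scale `1.4826 MAD`). The
   brightest surviving maximum is the pole; ties break deterministically
   toward the lowest linear index. Sub-voxel XY refinement uses a 3x3
   intensity-weighted centroid; Z comes from the intensity-weighted
   centroid of the stack column under the pole. The same column-centroid
   construction initializes the Z coordinate of every 2D detection (the
   projection discards Z, so some choice is required; a centroid is the
   natural moment estimator).
3. **Angular scanning.** The MIP is resampled around the pole into polar
   coordinates (bilinear interpolation, `Δφ = 2°`, `Δr = 0.5` voxel) and
   radially integrated into `I(φ)` after median subtraction. Line
   candidates are prominent peaks of `I(φ)` (prominence ≥ 25% of the
   maximum) that also clear a noise floor: the peak must exceed the median
   of `I(φ)` by 2x a robust scale estimated from the *below-median* bins
   only (microtubule signal only adds intensity, so the lower half of the
   angular function is a clean noise sample). Peak angles are refined to
   sub-bin accuracy by a parabola through the three bins around the peak.
4. **Length walk.** Along each peak angle the radius grows until the
   interpolated profile stays below `stop_factor` x background
   ("comparable to the background"; default factor 1.2) for three
   consecutive samples — requiring a run, not a single sample, stops
   single noise dips from truncating a line. The walk starts beyond twice
   the pole spot width, where the profile reflects the microtubule rather
   than the pole. Guesses outside the length cutoffs (default 0.3 µm to
   the image diagonal) are discarded.
5. **Bipolar spindles.** Otsu foreground, connected components, and a
   weighted principal-axis orientation of the largest component (the two
   largest are merged when a dim spindle splits the foreground into two
   pole blobs). The spindle poles are intensity-weighted centroids of the
   extreme high-intensity clusters along the axis; polar microtubules are
   then scanned from each pole, excluding directions along the spindle.
6. **Curve tracing.** Ridge orientation comes from the eigenvectors of the
   Hessian of the scale-smoothed MIP (a second-order orientation-tunable
   filter). The tracer steps along the local ridge direction (1 voxel per
   step), keeps direction consistency, and stops at background, image
   border, or a turn sharper than 90°. The traced path is condensed into a
   curve feature by fitting the parametric polynomial (degree 4 in XY, 1
   in Z), sampling its curvature, and fitting the Fourier model; the
   profile least-squares over `w` uses a grid search plus golden-section
   refinement, since the model is linear in all other coefficients.

## Optimization

Fitting minimizes the residual sum of squares between the rendered model
and the image over all voxels, with bounded trust-region
Levenberg-Marquardt (minpack.lm). Local passes optimize one feature at a
time with everything else frozen; a global pass then varies all parameters
including the background. Bounds: positions within the image plus a
2-voxel margin; widths within [0.5, 4]x and amplitudes within [~0, 10]x
their initial values; background within [0, 2x image max]. The amplitude
lower bound is deliberately left near zero (rather than a hard 0.1x
floor): a spurious feature must be able to fade out entirely, otherwise it
retains irreducible intensity and the removal test below would always keep
it.

Analytic Jacobians for spots and lines (derived from the closed-form
render and verified against central differences in the tests) make the
derivative-based passes cheap; curve features fall back to forward
differences on their own render. Two numerical choices keep the solver fast
without changing what is being minimized:

- **Informative-voxel masks.** Single-feature fits run on the feature's
  bounding box (plus an 8-voxel XY margin and the full Z range); the
  global fit runs on voxels within 3σ of any feature plus a regular
  1-in-7 background sample. Voxels outside these sets carry essentially no
  gradient information for the parameters being varied. All *reported* RSS
  values, and all f-tests, are computed on the full grid, and a fit is
  rejected (the initial model kept) if its full-grid RSS did not improve.
- **Line length scans.** The residual landscape along a line's axis has
  shallow local minima; before each derivative pass on a line the length
  is scanned on a 0.1 µm grid (amplitude profiled out in closed form), and
  the scan+refine pair is applied twice so the second scan sees the
  corrected direction.

**Feature-count selection.** The number of lines/curves is a
hyperparameter optimized in two phases. The addition phase proposes
candidates from the residual image (data minus fitted features, background
and noise left in place so the residual scans like an ordinary image):
angular-scan candidates plus *hotspot* candidates — lines from the pole
through bright residual maxima, which directly pin down both direction and
radius for short microtubules and for directions partially claimed by an
already-fitted neighbor. A candidate overlapping an existing line (within
~25° from the same pole) is fit jointly with it so the pair can split the
shared intensity. A candidate is kept only when the nested-model f-test
finds the RSS drop significant:

    F = ((RSS_simple − RSS_complex)/Δp) / (RSS_complex/(n − p_complex))

The removal phase deletes line/curve features whose RSS contribution is
insignificant, refitting overlapping partners first so a duplicate's twin
can re-absorb the shared intensity. Pole spots are never removed. The
final model is re-fit globally, preceded by a short per-line polish pass.

Selection is asymmetric. Additions are judged at a conventional
`alpha = 0.05`: a candidate is compared against a model that has not yet
been re-fit around it, so its F statistic understates its real
contribution and a permissive gate avoids discarding weak genuine
microtubules. After the addition phase an intermediate global re-fit lets
all features settle, and the removal sweep then prunes at a deliberately
strict `alpha_remove = 0.001`: the addition phase *searches* over
candidate positions and orientations, so the realized null distribution
of F for fitted noise features is inflated well above the nominal F
distribution (noise features reach F ≈ 1.5–3 where the nominal 5%
critical value is ≈ 1.8), while genuine microtubules separate at F ≈ 4
and above. The removal sweep visits features in ascending amplitude and
repeats until a full pass removes nothing, so a single kept feature
cannot shield junk further up the ordering. `f_test()` itself keeps the
conventional 0.05 default for direct use. Candidates are pre-screened
before any fit by a closed-form bound on their achievable RSS drop
(profiling the amplitude against the residual), which costs one render
and skips clearly hopeless proposals.

## Tracking

Features are linked frame to frame by a minimum-cost linear assignment
(Hungarian method with shortest augmenting paths, oracle-tested against
exhaustive enumeration) on anchor-point distances: spot centers, line and
curve free-end tips, with the end nearer the previous tip taken as the tip
(orientation consistency). Births and deaths are available at cost
`max_link_cost` (default 1 µm), so no realized link ever costs more than
that. A second stage closes gaps of up to `max_gap` frames (default 1)
between track ends and starts. Tracks observed in fewer than `min_frames`
frames (default 3) are pruned entirely — single-frame features are treated
as spurious. No motion model and no merge/split events are attempted.

## The simulator and the SNR definition

The simulator is the validation substrate: it generates monopolar stacks
(a pole spot plus 0–7 straight microtubules of 0.5–3 µm at uniform random
angles, mostly in-plane: |dz|/L ≤ 0.25), bipolar spindles (two poles joined
by a bright bundle line, separation 2–3.5 µm), and astral geometries (a
bipolar spindle plus curved filaments), on 64 x 64 x 7 voxel grids at
0.1/0.1/0.5 µm. Microtubule amplitudes are *peak centerline brightnesses*
(default 5, pole 15, spindle bundle 15, arbitrary units), implemented by
rescaling the line-model amplitude so the rendered peak matches; a
fluorophore-labeled polymer has constant brightness per unit length, so
longer microtubules must not be dimmer — and the equivalent line-model
amplitude is stored in the ground truth so re-rendering the truth
reproduces the clean image exactly.

SNR is defined as the mean background-subtracted image intensity over a
microtubule's footprint (voxels within 1σ of its centerline, excluding the
immediate neighborhood of pole spots, whose fluorescence belongs to the
pole) divided by the background, taken as the median intensity of the
image; the image SNR averages over microtubules. This definition is
scale-invariant, grows without bound as noise vanishes, and admits values
below 1 — all three properties are needed for sweeps that reach SNR 0.75.

Noise is Poisson-like photon noise with the *background as the noise
source*: the clean render sits on a uniform background rate `b` and each
voxel receives Gaussian noise with variance `gain x rate` (gain 1 by
default), clipped at zero. The target SNR fixes `b` from the clean
microtubule signal; raising the background photon rate simultaneously
raises the noise floor and lowers the SNR, as in low-excitation live-cell
imaging where amplitudes stay fixed and only the background varies. The
calibration is exact in expectation: over 100 seeds at target 1.5 the mean
realized SNR lies within 2% of target (asserted in the tests).

**What the benchmarks do not show.** The simulator shares the renderer
with the fitting code, so benchmark results certify the detection,
selection and localization machinery — not the adequacy of the Gaussian
model for real optics. Real data adds depth-dependent PSF broadening,
uneven cytoplasmic background, camera artifacts, and neighboring cells,
none of which are emulated. Voxel intensities are modeled at voxel centers
rather than integrated over voxel volumes; both the simulator and the fit
use the same convention, so this cancels in the benchmarks but is an
approximation on real data.

## Validation protocol

`snr_sweep()` runs the full per-frame pipeline on freshly simulated stacks
across SNR levels, classifies each image with greedy nearest-first
one-to-one tip matching at 0.5 µm, and aggregates correct/spurious/missed
rates, mean per-axis errors (in pixels of that axis: 0.1 µm XY, 0.5 µm Z),
and the 3D pixel-normalized error — the Euclidean norm of the per-axis
pixel errors, so a value below 1 means sub-pixel localization in the
combined sense (the most natural reading of a "mean 3D error" plotted
against a sub-pixel threshold when the axes have different pixel sizes).
The problem sizes used in the shipped acceptance run — 100 images at SNR
1.25 and 50 per level across {0.75, 1, 1.25, 1.5, 3, 5} — were chosen as
the smallest sets at which the binomial/mean sampling error is clearly
smaller than the margins being tested.

Per-image seeds are derived deterministically from a base seed
(`base + 7919 (level-1) + rep`), so every run is reproducible and any
single image can be regenerated in isolation.

## Dynamic-instability analysis

Track length series are segmented into polymerization and depolymerization
events: maximal contiguous runs of at least 3 points whose linear fit has
R² ≥ 0.8 and whose fitted length change is at least 0.5 µm in magnitude.
Runs extend greedily while the fit criterion holds and are then trimmed
from the tail while trimming improves R² (the greedy extension otherwise
swallows the first point of the next phase); adjacent events share at most
the boundary point, which belongs to the earlier event. The slope of the
fit is the event speed; for every polymerization event immediately followed
by a depolymerization, the fitted length change is recorded as the
polymerized length preceding that catastrophe. A flat or noise-only series
produces no events (R² rejects it), and time-reversing a series swaps the
two event kinds.

## Known limitations

- One cell/structure per cropped stack; no multi-cell segmentation.
- The angular scan resolves microtubules separated by more than roughly
  the PSF's angular width at their mean radius; nearly collinear pairs are
  initially merged and are only split if the residual-driven addition
  phase proposes the second member.
- Curves are planar-bend only (Z linear); strongly 3D-curved filaments
  would be mis-modeled.
- The f-test selection level is calibrated for the search-inflated null
  described above; applications with very different voxel counts or noise
  structure may need to revisit `alpha`.
- Amplitudes are not calibrated to microtubule counts per bundle;
  brightness comparisons across bundles are qualitative.
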
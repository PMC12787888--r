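---
title: "Measuring corn ear heights from RGB-D detection streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring corn ear heights from RGB-D detection streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cehd)
```

## The measurement problem

A fresh-corn harvester needs to know, per plant, how high each ear sits
above the ground so the header can be positioned before the machine
reaches it. `cehd` implements the post-detection half of such a system.
The input is what a detector on a row-following RGB-D platform produces:
per-frame bounding boxes with confidences, aligned depth maps (16-bit,
millimeter units, 0 = invalid, the RealSense convention), and a camera
description — here a camera mounted 1.8 m above ground, pitched 45°
downward, traveling along the row at roughly 0.3–0.5 m lateral offset.
The output is a set of stable per-ear tracks and, for each, a robust
estimate of ear height above ground in meters.

Four stages compose the pipeline, in order:

1. **Score refinement** (`apply_aqe()`): box-quality statistics from the
   detector's discretized regression distributions, fused with the
   classification score under an occlusion-aware gate.
2. **Row filtering** (`filter_by_depth()`): removal of detections that
   belong to the next planting row using one range threshold (0.5 m at
   0.6 m row spacing).
3. **Tracking** (`run_tracker()`): a DeepSORT-style association cascade
   whose state estimator is a constant-velocity Kalman filter with
   confidence-adaptive, per-dimension observation noise and an
   exponentially smoothed reported center.
4. **Height solving** (`estimate_height()`): back-project the depth
   pixels inside each tracked box, reject depth outliers, take the median
   of the per-point heights above ground.

## The adaptive filter

The track state is the 8-vector $(x, y, a, h, \dot x, \dot y, \dot a,
\dot h)$ — box center (px), width/height aspect ratio, box height (px),
and their per-frame velocities — with a constant-velocity transition and
the usual linear observation of $(x, y, a, h)$. What distinguishes the
filter is the observation-noise covariance, rebuilt at every update from
the detection confidence $c \in [0, 1]$:

$$
\sigma_x = \max(1-c,\ \varepsilon)\, w\, h_{t-1}, \quad
\sigma_y = \max(1-0.8c,\ \varepsilon)\, w\, h_{t-1}, \quad
\sigma_a = \max(1-0.5c,\ \varepsilon)\cdot 0.1, \quad
\sigma_h = \max(1-c,\ \varepsilon)\, w\, h_{t-1},
$$

with $R_t = \mathrm{diag}(\sigma_x^2, \sigma_y^2, \sigma_a^2,
\sigma_h^2)$. Confident detections therefore pull the state hard; dubious
ones barely perturb it. Parameters, all exposed in `filter_params()`:

* `w = 0.05` — the position normalization weight. The noise scales as
  $w\,h_{t-1}$, i.e. proportionally to apparent target size; $1/20$ is
  the canonical DeepSORT scaling and keeps the adaptive noise equal to
  the fixed baseline at $c = 0$.
* `eps = 0.01` — the noise floor, preventing a vanishing $R_t$ as
  $c \to 1$.
* `alpha = 0.7` — the center-smoothing coefficient (below); larger is
  more stable, at the cost of responsiveness.
* Process noise follows the DeepSORT convention (position std $h/20$,
  velocity std $h/160$ per frame, aspect $10^{-2}/10^{-5}$), computed
  from the pre-propagation height.
* The control term $B u_k$ of the propagation equation is carried in the
  parameter object but identically zero: tracking has no control input.

`adaptive_noise()` uses the *pre-update* height estimate $h_{t-1}$, as
the time indexing of the noise law requires. Updates use the plain
gain/correction equations with a symmetrized posterior covariance; the
test suite verifies exact agreement (to $10^{-10}$ over 200 cycles) with
an independently coded textbook filter when $R$ is held constant.

### Center smoothing

Reported centers are exponentially smoothed,
$s_t = \alpha\, s_{t-1} + (1-\alpha)\, x'_t$, independently in $x$ and
$y$. Applied verbatim to a target moving at constant velocity $v$, that
recursion has a steady-state lag of $\frac{\alpha}{1-\alpha} v$ — at
$\alpha = 0.7$ and typical platform-induced image motion of ~10 px/frame
that is ~25 px, more than the box jitter the smoothing is meant to
remove, enough to break IoU-0.5 matching against ground truth, and
self-defeating for depth extraction (the box slides off the ear). Since
every box in this application moves with the platform, `kf_step()`
therefore blends against the *velocity-propagated* previous value:

$$ s_t = \alpha\,(s_{t-1} + \hat v_t) + (1-\alpha)\, x'_t . $$

For a static target ($\hat v = 0$) this is exactly the plain recursion;
for constant velocity it is unbiased while still averaging down
observation jitter. `smooth_center()` itself remains the literal
primitive ($\alpha = 0$ identity, $\alpha = 1$ freeze), and the variance
reduction on static noisy tracks is asserted over 50 seeds for
$\alpha \in \{0.3, 0.5, 0.7\}$ in the test suite. The smoothed center
feeds reported boxes and the height solver only; gating and association
use the raw filter state, keeping the filter's statistical consistency.

## Association

The matcher is the standard DeepSORT cascade — the filter and the
embedder are where this pipeline differs from stock DeepSORT, not the
matcher. Confirmed tracks are matched in order of increasing time since
last update; the cost is the minimum cosine distance between the
detection embedding and the track's gallery (capacity 100), gated by the
squared Mahalanobis distance of the innovation under $H P H^\top + R_t$
(chi-square 0.95, 4 df, 9.4877) and by the appearance gate (0.2).
Because $R_t$ is confidence-adaptive, low-confidence detections get
looser motion gates — a deliberate consequence of the adaptive filter.
Leftover tentative and just-missed tracks fall back to IoU matching
(threshold 0.3). Assignments minimize total cost via an exact Hungarian
solver (`solve_assignment()`, validated against brute-force enumeration);
ties resolve to the lowest track id then detection index, which together
with the package's isolated RNG streams makes every run bit-reproducible.
Tracks lacking embeddings run motion-only, so the tracker works on plain
`frame,id,x,y,w,h,conf` files. Lifecycle: confirmation after `n_init = 3`
hits, deletion after `max_age = 30` missed frames — all configurable,
none prescribed by the scientific content.

## Score refinement and its gate

Each box side carries a discretized regression distribution (`n_bins =
16`, the prevailing distributional-regression convention). After a
per-side softmax, the top-`k` probabilities and their mean (`k = 4`,
common practice for distribution-based quality estimation; no specific
value is mandated by the method) form a $4(k+1)$ statistic, mapped by a
small MLP (one hidden layer, width 64, ReLU; weights are injectable and
no training code ships) to a quality score $Q$. Fusion with the
classification score $S$ is either additive, $S' = S + Q\,\sigma(S)$, or
multiplicative, $S' = S\,\sigma(Q)\,\sigma(S)$, where $\sigma(S)$ is the
occlusion factor. The stage switch between the two forms is a
training-time schedule; as training is out of scope the pipeline default
is the converged-model (multiplicative) behavior, with the mode exposed.
Boxes are emitted when $S' \ge 0.75$ (inclusive).

One algebraic consequence deserves attention: with probability-valued
scores, $\sigma(S) \le 0.731$ for $S \le 1$, so the multiplicative form
can never reach the 0.75 gate — it is a pure suppressor. That is
precisely the designed behavior for low-confidence/high-quality boxes
(they stay suppressed until occlusion clears), but a pipeline that wants
the multiplicative form to *emit* must feed the occlusion factor the
classification logit instead (`logit_input = TRUE`, giving $O = S$ on
the probability scale). The additive form has no such restriction.
`lqe_score()` (the plain $S' = S + Q$ baseline) is kept unclipped; a
`clip` option bounds fused scores to $[0,1]$ when a downstream consumer
requires it.

## Row filtering geometry

The platform straddles the inter-row space, so everything in the next
row sits roughly one row spacing (0.6 m) farther from the camera; a
single 0.5 m range threshold should keep the target row entirely and
remove the far row entirely. The subtlety is *which* range. The raw
camera-frame depth of an ear at height $H$ seen by a camera at mount
height 1.8 m pitched 45° down is
$z_c = d\cos 45° + (1.8 - H)\sin 45°$ for lateral offset $d$: at
$d = 0.4$ m and $H \in [0.8, 1.5]$ m that spans 0.49–0.99 m, overlapping
the far row's 0.92–1.41 m. No raw-depth threshold separates the rows,
because $z_c$ mixes the lateral offset with the height-dependent
vertical drop. The quantity that the row geometry actually controls is
the horizontal ground-plane range $z_c\cos\alpha - y_c\sin\alpha$, which
equals the camera-to-row distance for any ear height (and reduces to
$z_c$ exactly for a level camera). `filter_by_depth()` therefore
compares the ground range whenever a camera model is available, and
falls back to raw depth without one. With the ground range, 0.4 m vs
1.0 m separate cleanly at 0.5 m for every ear height, which is what the
acceptance suite asserts over 10 seeded scenes.

The representative box depth is the median over the centrally shrunk box
(`shrink_fraction = 0.6`): ear boxes include background at leaf/sky
depth near their edges, and the median of the central region is robust
to both. Boxes with fewer than `min_valid_pixels = 10` valid depths pass
through flagged rather than being dropped — the filter removes confirmed
far rows, it does not discard uncertain detections.

## Height solving

For each reported (smoothed) track box: back-project every valid depth
pixel of the centrally shrunk box (0.8) through the pinhole model,
reject depth outliers, convert each surviving point to height above
ground with $H = 1.8 - (y_c\cos\alpha + z_c\sin\alpha)$, and take the
median (even counts average the middle two). Choices:

* **Outlier rule**: keep $|z - \mathrm{med}(z)| \le k\cdot\mathrm{MAD}(z)$
  with $k = 3$; the MAD is scale-free and stable at the few hundred
  pixels of an ear box, and is floored at 1 mm so constant patches keep
  all points.
* **Median over heights, not depths**: only the median of ground-frame
  heights yields an absolute height above ground after the extrinsic
  transform; the camera-frame-y variant is available behind
  `use_camera_y` for comparison.
* **Smoothed boxes**: box stability directly limits depth-extraction
  accuracy, which is the reason the tracker smooths centers at all, so
  the solver consumes the smoothed boxes.
* Estimates outside $[0, \text{mount height} + 1]$ m are rejected as
  insane; frames with fewer than `min_points = 20` surviving points are
  skipped and the track keeps its last estimate. Per-track series get a
  running median (`smoothing_window = 5`) and a median/MAD summary.

## The scene simulator

`generate_scene()` builds the geometry the pipeline is designed for: a
target row at 0.4 m lateral offset, a far row 0.6 m beyond, ears with
uniform true heights in 0.8–1.5 m spaced ~0.3 m along the row, a camera
(1.8 m, 45°, 320x240, fx = fy = 200) advancing 0.02 m/frame (~0.6 m/s at
30 fps, a realistic platform speed). Ears render into depth maps as
constant-depth rectangles — the pipeline consumes only in-box depth
statistics, so rectangles with multiplicative depth noise (1%) and
background-pixel contamination (20%) are a sufficient test double.
Detections perturb true boxes with Gaussian noise of std
$\kappa(1-c)h$, $\kappa = 0.05$: this matches the adaptive filter's
noise model *by design*, so the three-way raw/fixed/adaptive comparison
is run under conditions where the adaptive law is correctly specified.
Occlusion windows either drop detections entirely or degrade them
(confidence forced to the low end, noise tripled) over a configurable
frame range; the shipped benchmark uses frames 40–60 of a 100-frame
sequence. Embeddings come from per-identity Gaussian clusters on the
unit sphere (dim 16, std 0.1), informative in the way a trained
re-identification network's features are. Ears whose boxes are more than
30% occluded by nearer boxes are neither annotated nor detected,
mirroring field annotation protocols that exclude heavily occluded ears.

What the simulator does **not** emulate: leaf/stalk geometry and partial
within-box occlusion, lighting, correlated detector failure modes,
rolling shutter, depth shadows and material-dependent depth error.
Passing tests on this simulator demonstrate the estimation machinery is
correct under its stated noise model — not field performance.

All randomness flows through `local_rng()` streams seeded from the scene
seed, so scenes, depth frames, and detections are bit-reproducible and
never touch the caller's RNG state.

## Problem sizes and numerical choices

The test and acceptance workloads use 320x240 frames, scenes of 1–20
ears over 10–340 frames, 50-seed benchmarks for the filter-ordering and
identity-recovery properties, and 10-seed sweeps for row filtering —
sizes chosen so the full suite runs in about a minute while every
property is still exercised end to end. Depth images are written as
single-channel 16-bit TIFF (lossless for the full integer range;
16-bit PNG is accepted on input). Matrix updates symmetrize the
posterior covariance; the innovation solve raises a descriptive error on
singular covariances rather than returning garbage. Box rasterization is
half-open with 0-based pixel centers at integers. MOT evaluation carries
previous-frame correspondences forward before optimal rematching,
counts identity switches against the last known assignment, and scores
identity F1 by a trajectory-level optimal assignment on per-frame
overlap counts; all of it is cross-checked against a brute-force
enumeration reference in the tests.

## Limitations

* The quality head is untrained; shipped weights are for exercising the
  code path, and quality scores on real data require the detector's own
  trained head.
* Appearance embeddings are an input contract; the package does not
  compute them from pixels.
* Mount height and pitch are configuration, not estimated from data; a
  mis-specified pitch biases every height by roughly
  $z\,\Delta\alpha\,\cos\alpha$.
* The tracker is single-class and assumes an approximately constant
  platform velocity between frames; camera-motion compensation is out of
  scope.
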
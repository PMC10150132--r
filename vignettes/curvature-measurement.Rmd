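---
title: "Measuring shaft curvature from 2D silhouettes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring shaft curvature from 2D silhouettes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvemeter)
```

## The measurement model

`curvemeter` quantifies the curvature angle of a bent, roughly
cylindrical shaft — the motivating case is penile curvature assessment
in hypospadias/chordee surgery planning — from a 2D photograph or a
binary silhouette. The shaft is modelled as three zones along its
length: a straight **distal** zone (toward the tip), a **curvature**
zone where all bending happens, and a straight **proximal** zone
(toward the base). A mid-axis line is fitted through each straight
zone; the endpoints of the two axes are the four landmarks DMD_top,
DMD_bottom (distal pair) and PMD_top, PMD_bottom (proximal pair). With
axis vectors $v_1 = (x_1-x_2,\; y_1-y_2)$ and
$v_2 = (x_3-x_4,\; y_3-y_4)$, the angle is

$$\theta = \cos^{-1}\!\left(\frac{v_1 \cdot v_2}{\lVert v_1\rVert\,
\lVert v_2\rVert}\right) \in [0^\circ, 180^\circ].$$

The cosine argument is clamped to $[-1, 1]$ before the arccosine so
floating-point rounding can never produce `NaN`. Two landmark pairs
(rather than three points through a bend apex) make the definition
valid for both hinge-type bends (a point vertex) and arc-type bends (a
distributed circular arc): for an arc there simply is no single apex a
3-point scheme could use. With the package's ordering convention —
DMD_top distal-most, PMD_bottom proximal-most, the inner points
adjacent to the curvature zone — both vectors point "backwards" along
the shaft, a straight shaft gives $\theta = 0$, and $\theta$ is the
curvature angle itself.

Key assumptions: the shaft is imaged roughly laterally; the silhouette
is a single connected, hole-free region with an approximately constant
width; each of the two straight zones covers at least 15% of the
midline; bending is confined to one contiguous mid-region.

## Pipeline stages

1. **Localization** (`detect_shaft`, `crop_to_window`): Otsu threshold,
   morphological opening (disc, radius 3 px), connected components.
   Each component above an area floor becomes a box with confidence =
   area / largest area; boxes at or below the 0.75 confidence floor are
   discarded, so exactly the dominant component survives in the
   single-object setting. The winning box is expanded by a margin
   (default 5%), letterboxed to a square (aspect preserved, background
   fill) and bilinearly resampled to a 256 x 256 window; the exact
   affine map is attached so landmarks can be carried between frames
   in either direction.
2. **Segmentation** (`segment_shaft`): Otsu threshold, opening +
   closing (disc, radius 3 px), largest component, hole filling. Both
   threshold stages assume the shaft brighter than the background, as
   the renderer produces.
3. **Landmarks** (`extract_midline`, `partition_zones`,
   `derive_keypoints`): described next.
4. **Angulation** (`axis_vectors`, `angle_between`, `mae_report`).

Running from a manually segmented mask skips stages 1–2 entirely
(mask-input mode).

## Midline extraction

The mid-axis is computed by Zhang–Suen thinning of the mask, then
taking the longest geodesic path between skeleton endpoints on the
8-connected pixel graph (edge weights 1 and $\sqrt 2$). Side branches
are pruned implicitly by the path choice; if any branch hangs off the
main path by more than 10% of its length the mask has no dominant axis
and the stage errors rather than guessing. Degenerate inputs error
explicitly: masks thinner than ~3 px (no interior), blob-like masks
whose main path is shorter than three times the maximal inscribed
radius (e.g. a disk), and multi-component masks.

Thinning systematically retracts — and sometimes hooks — the skeleton
near a rounded end cap. Each path end is therefore refined: about half
a cap radius is trimmed, then the end is extended along its local
tangent to the cap center, located with the distance transform (inside
a cap, distance-to-background falls off linearly toward the silhouette
end, so the cap center is where the profile starts to drop). The path
is smoothed with a 5-point moving average (shrinking windows at the
ends). The recorded ground-truth midline of a phantom likewise runs cap
center to cap center, which makes the two directly comparable; each
terminal landmark thus sits one cap radius inside the physical
silhouette end, a deliberate convention that keeps the rounded cap from
biasing the axis.

**Orientation.** Which end is distal cannot be inferred from a
constant-width silhouette. `extract_midline` accepts an explicit rule
(`top`/`bottom`/`left`/`right`), a point hint (the end nearer the hint
is distal — pipelines driven by an annotated manifest use the
ground-truth DMD_top for this, exactly as a human annotator fixes the
correspondence), or `auto`, which picks the end with the smaller local
width (tip taper) and falls back to a deterministic top-left rule on
ties. Note that the angle itself is invariant under orientation
reversal (both vectors flip roles); only landmark correspondence — and
therefore NME — depends on it.

## Zone partition

Along a straight–bend–straight shaft the tangent angle is a
piecewise-linear function of arclength: flat, then a ramp (a step for a
hinge; constant slope for an arc), then flat. The two boundaries are
found by an exact least-squares change-point fit of that
flat–ramp–flat profile (prefix sums make the scan over all boundary
pairs cheap), with each straight run constrained to at least 15% of the
arclength. This first-order formulation locates arc boundaries far more
precisely than any perpendicular-deviation rule, whose error grows as
$\sqrt{2\varepsilon/\kappa}$ for curvature $\kappa$ and noise
$\varepsilon$.

Raster quantization makes individual tangents noisy (a few degrees), so
the profile is smoothed by a 5-point moving average before fitting.
Smoothing plus chord-based tangent estimation plus the skeleton's
corner rounding smear a hinge's step into a short ramp whose width
scales with the stroke half-width $r$; the package models this
explicitly with a smear scale `blur = max(7 * spacing, 1.1 * r)`.
Hinge-vs-arc assignment is then a model comparison: the profile is
refitted with the ramp width capped at `2 * blur` (the "hinge" model)
and

- if the hinge model's SSE is within 10% of the free fit, the bend is a
  point vertex: the curvature zone collapses to the narrow ramp's
  midpoint;
- if the hinge model is more than 50% worse, the free boundaries stand
  (a genuine arc);
- in between — shallow bends where the data genuinely cannot
  distinguish a smeared step from a gentle arc — the free ramp is
  shrunk by `blur` on each side. This bounds the landmark error under
  *either* true shape to about the smear width, instead of risking a
  half-ramp error from a wrong hard choice.

A midline whose whole tangent range stays within twice the straightness
tolerance (default 3°, chosen with margin below the 5° annotation-QA
bound used when verifying labels in this setting) is treated as
straight: the zones meet at the midpoint and the curvature zone is
empty. If a fitted flat run still shows gross tangent spread (RMS above
three times the tolerance), the shaft has no usable straight zone and
the stage errors.

`derive_keypoints` fits a total-least-squares (principal-axis) line to
each straight zone's midline points and perpendicularly projects the
zone's arclength endpoints onto it. The curvature-adjacent 15% of each
zone is excluded from the fit (not from the projection) so residual
corner contamination cannot tilt the axis.

## Evaluation metrics

- **Detection**: single-class AP by confidence-ranked all-point
  precision–recall integration (area under the stepwise precision
  envelope), greedy matching with each ground truth used at most once,
  ties broken by higher IoU then input order; mAP@0.5 and the
  0.5:0.95:0.05 sweep. The all-point interpolation is a deliberate
  choice documented here because detector toolkits differ on it.
- **Segmentation**: accuracy, foreground IoU $= TP/(TP+FP+FN)$, DSC
  $= 2TP/(2TP+FP+FN)$, and a class-frequency-weighted two-class IoU.
  Both IoU variants are reported because in 256 x 256 crops foreground
  and background are roughly balanced and published "IoU" columns are
  ambiguous between the two; the printed-formula foreground form is the
  headline `iou`. The identity DSC = 2·IoU/(1+IoU) is enforced by test.
- **Landmarks**: NME = mean Euclidean landmark error divided by the
  ground-truth DMD_top–PMD_bottom distance, normalized per image and
  then averaged. The normalizer comes from ground truth, never from
  predictions — standard landmark-benchmark practice, and it keeps NME
  scale- and rotation-invariant.
- **Angles**: per-model MAE plus two overall summaries, because the two
  common definitions disagree: `mae_pooled` (mean per-image absolute
  error over all images, the headline) and `mae_model_mean` (absolute
  error of each model's averaged prediction, then averaged). Both are
  always reported.

## The phantom generator

`make_phantom` sweeps a constant-width stroke along an analytic
midline — straight segment, then a hinge vertex or a circular arc whose
turning angle is exactly the requested curvature, then a straight
segment — by exact distance-to-polyline rasterization (round caps arise
naturally; flat tips clip at the cap plane). Ground truth is analytic:
the angle from the ground-truth keypoints reproduces the spec angle to
machine precision, which the tests assert at 1e-9°.

`make_dataset` emulates a physical-model photography protocol: a small
set of distinct models with nominal angles spread evenly over a range
(default 18–86°, about half hinge and half arc, interleaved), many
scenes per model, each scene with its own pose. Per-scene jitter maps
the protocol's two camera axes to an in-plane rotation offset drawn
from (−5°, 5°) and a foreshortening tilt drawn from (0°, 20°) that
scales the geometry along image y by cos(tilt). The jittered truth is
recomputed after projection, so every scene's mask, keypoints, box and
`angle_deg` stay exactly self-consistent, while `model_angle_deg` keeps
the nominal angle. Scoring predictions against nominal angles therefore
includes genuine projection spread, just as photographing a physical
model from off-axis positions does. Model geometry follows the physical
scale of the emulated models (about 1.5 cm wide, 5–6 cm long, scaled to
pixels): distal length 50–68 px, distal:proximal ratio 0.8–1.2, width
0.25 x distal length, arc length 25–40% of the combined straight
lengths, inside 256 x 256 rasters.

Rendering (`render_scene`) is geometry-preserving: intensity contrast
(foreground 0.75 over background 0.25), optional low-amplitude textured
background, optional Gaussian intensity noise, under a single seed that
makes every output byte-reproducible. What the phantoms deliberately do
**not** emulate: skin texture and specular lighting, perspective
distortion of the width profile (the stroke width stays constant after
projection), soft-tissue irregularity, occlusion, and the anatomical
width taper of a real organ. Passing benchmarks on phantoms therefore
validates the geometry pipeline under controlled conditions; it does
not certify performance on clinical photographs, where segmentation is
much harder.

## Numerical choices and problem sizes

Coordinates are 0-based with x rightward, y downward, pixel centers at
integers, and sub-pixel landmark positions. Boxes store
`x_max = rightmost pixel + 1` so width equals pixel count. All
stochastic draws flow from a single integer seed; reruns are
byte-identical, and the per-scene render seeds are recorded in the
dataset. Benchmarks in the test suite and the acceptance script use 9
models x 50 masks (landmark/angle stages) and 10 models x 20 rendered
scenes with intensity noise at 5% of the contrast gap (detection and
segmentation stages) — sizes chosen to mirror the emulated protocol's
order of magnitude (around a hundred pictures per model, nine models)
while keeping a full run to a few minutes on one CPU.

## Known limitations

- Orientation of a constant-width shaft is not identifiable from shape
  alone; unannotated use should supply `--distal` or rely on a genuine
  tip taper.
- Very shallow bends (around 10° and below) sit in the intrinsic
  hinge/arc ambiguity band; the inner landmarks then carry a
  smear-scale uncertainty, though the angle itself remains accurate.
- A genuine arc shorter than about twice the smear scale (roughly the
  shaft width) is treated as a hinge.
- Flat-tip phantoms place the ground-truth terminal landmark at the
  face center, which medial-axis extraction cannot reach exactly; the
  rounded default avoids this.
- The threshold-based localization/segmentation stand-ins assume
  bright-on-dark contrast; they are contracts for the pipeline, not
  clinical-grade segmenters.
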
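---
title: "Locating tea-shoot picking points from side-view images"
author: "teapick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating tea-shoot picking points from side-view images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teapick)
```

## The problem

Premium tea is picked as "one bud one leaf": the young shoot tip is cut from
the stalk a fixed distance below the point where the bud and its leaves
diverge. Cutting too high shreds the bud; cutting too low leaves a long
stalk that downgrades the leaf. A mechanized picker that combs the stalks
into an upright strip and images them **from the side** only needs two
coordinates per shoot — horizontal position X and height Z — because the cut
is a horizontal shear at a chosen height while the carriage advances at
constant speed.

`teapick` implements the 2D side-view localization and control workflow as a
desk-testable pipeline:

1. **Synthetic scenes** (`build_scene()`, `render_scene()`) with exact
   world-coordinate ground truth;
2. **Skeletonization** (`binarize()`, `thin()`) by the two-subiteration fast
   parallel thinning rules;
3. **Picking-point localization** (`find_intersection()`, `trace_stem()`,
   `fit_growth_curve()`, `locate_pick_point_px()`, `pixel_to_world()`,
   orchestrated by `locate_all()`);
4. **S-curve motion planning** (`scurve_params()`, `plan_cycle()`,
   `integrate_profile()`, `schedule_row()`);
5. **Trial scoring** (`localization_errors()`, `run_trial()`,
   `success_rates()`, `detection_metrics()`).

## The synthetic scene model

Real deposited imagery for this task does not exist, so the package carries
a generator whose defaults encode the measured biometry of harvest-ready
shoots:

| parameter | symbol | default range | units |
|---|---|---|---|
| shoot length | L | 27.5–30.2 | mm |
| stalk diameter | Φ | 1.1–2.3 | mm |
| pickable stalk region | A₂ | 11.2–15.3 | mm |
| leaf insertion angle | β | 45.6–54.2 | degrees |
| tip height above canopy | — | 50–110 | mm |
| inter-tip spacing | — | 50–80 | mm |

All parameters are drawn uniformly within their intervals (only ranges are
known, so a uniform draw is the minimal-assumption choice), from a single
explicit seed. The stem is modelled as a single-bow quadratic from the tip
down to the canopy, with a lateral bow amplitude of 0–3 mm: field error
reports attribute localization error chiefly to shoot bending, so the
generator must bend its stems, and a quadratic is the simplest shape that
exercises the curve-fitting stage. Two leaves attach exactly at the tip,
pointing down and outward at ±β from the stem axis, with a sine width
profile that tapers to zero at the attachment — this makes the leaf/stem
junction the topmost multi-branch point of the skeleton, which is what the
scan step detects. The bud is a small blob (radius 1.2 mm) centred on the
tip, so the area above each tip is blank as in a strip-clamped row. The
"optimal picking region" A₁ is a named concept with no quantified extent
anywhere; it is carried as an annotation only.

Rendering uses 5 px/mm on a 196 mm-high window, giving a 980-pixel-high
image. These two constants tie the synthetic scenes to the reference
calibration (`Hs = 196` mm, `Ht = 980` px), under which 1 px = 0.2 mm and
the 4 mm offset is exactly 20 rows.

What the generator deliberately does **not** emulate: photometric realism,
lighting variation, motion blur, occlusion by large leaves, and detector
noise (boxes are ground truth). Passing the desk experiment therefore
demonstrates the geometric correctness of the localization chain — not
field robustness of detection, which requires a trained detector and real
imagery.

```{r scene}
truth <- build_scene(3, seed = 7)
truth
scene <- render_scene(truth, seed = 7)
scene
```

## Thinning

The skeleton is computed by the classical two-subiteration parallel
thinning scheme. For a foreground pixel with clockwise neighbour ring
P2..P9 (north first), let B be the number of foreground neighbours and A
the number of 0→1 transitions around the ring. A pixel is deleted when
`2 ≤ B ≤ 6`, `A = 1`, and the subiteration's directional products vanish
(subiteration 1: `P2·P4·P6 = 0` and `P4·P6·P8 = 0`; subiteration 2:
`P2·P4·P8 = 0` and `P2·P6·P8 = 0`). Both subiterations use the grid state
frozen at their start (parallel semantics) and repeat until nothing is
deleted, so `thin()` returns a fixpoint of the rules. The border is padded
with a one-pixel background ring, which makes the neighbour rules total.

Two behaviours of these rules are worth knowing. First, they preserve the
connectivity of elongated structures — stems and leaves — which is what the
pipeline relies on. Second, they erase small *symmetric* blobs entirely: an
isolated 2×2 block satisfies subiteration 1 at all four pixels
simultaneously, and a small round blob erodes to such a block and vanishes
with it. The test suite asserts both behaviours explicitly; the
property-based connectivity tests therefore draw organ-like masks (strokes
with attached blobs) rather than isolated dots. The binarization default is
Otsu's threshold (parameter-free and adequate for high-contrast strip
imagery), with a fixed-threshold override.

## Localization

Per detection box the pipeline crops (2 px pad), binarizes, thins, and then:

1. **Intersection scan.** Rows are scanned top to bottom inside the box;
   the scan stops at the first row with ≥ 2 skeleton pixels — where the
   leaf branches diverge from the stem. Within a 3-row window below the
   stop row, a pixel with skeleton degree ≥ 3 (the actual branch node) is
   preferred; otherwise the pixel nearest the stop row's median column is
   taken. A skeleton with no multi-pixel row (leafless, degenerate) falls
   back to its lowest single-pixel row and is flagged.
2. **Stem trace.** An 8-connected walk descends from the intersection. At
   branchings a 12-step greedy look-ahead scores each branch by net row
   progress minus net column drift; the near-vertical stem scores ~depth
   while a leaf branch at ≥ 45° scores ~0, so the stem wins regardless of
   which branch offers the immediate downward pixel. One-row back-steps are
   allowed only when the look-ahead confirms the branch heads downward
   (skeleton staircases around the junction); persistent climbing stops the
   walk.
3. **Growth curve.** Columns are fitted as a polynomial in the row
   (degree 3 by default, reduced automatically for short traces, constant
   for perfectly vertical stems). Rows are centred before fitting for
   numerical stability.
4. **Offset and calibration.** The picking point is the curve evaluated
   `offset_mm · Ht / Hs` rows below the intersection — 4 mm *toward the
   stalk base*. (With Z increasing downward, "reducing" the vertical
   coordinate would literally move up into the bud; the cut must land on
   the stalk below it, so the offset is applied downward.) The vertical
   drop convention matches the calibration, which maps vertical pixels to
   millimetres linearly (`Zs = Zt · Hs / Ht`); an arc-length offset along
   the traced skeleton is available behind `locate_config(arc_length_offset
   = TRUE)` for strongly bowed stems. Pixel indices are 0-based; index
   `i` converts to world units at the pixel centre `i + 0.5`.

The field device narrows its view to a 200 px central strip when operating
on a moving row; `locate_config(fov_width_px = 200)` reproduces that
filter. It is off by default because a static desk scene is fully visible —
enabling it would silently drop every off-centre box of a wide scene.

```{r locate}
calib <- camera_calibration(Ht = scene$image_height_Ht)
pts <- locate_all(scene$image, scene$boxes, calib)
pts
localization_errors(pts, truth)$errors
```

## Motion planning

The picker rides a vertical track on a carriage that advances at constant
horizontal speed V. A vertical move of length S is planned as an S-curve
acceleration over a fixed ramp `S1 = 0.04` m, a uniform segment
`Sy = S − 2·S1` at `vlmax = 0.12` m/s, and the mirrored deceleration ramp.
The ramp is the logistic

  V(s) = vl0 + (vlmax − vl0) / (1 + e^(−a(s−b)))

which only reaches its asymptotes at infinity, so the package pins it with
a boundary tolerance `eps` (default 0.01): `b = S1/2`,
`a = 2·ln((1−eps)/eps)/S1`, giving `v(0) = eps·vlmax` and
`v(S1) = (1−eps)·vlmax` exactly. The published constants `a = 0.0067`,
`b = 0.02` do not reach `vlmax` within `S1` under any consistent unit
reading (direct evaluation gives v(S1) ≈ 0.060 m/s, half the ceiling); the
stated boundary condition — full speed after one ramp — takes precedence,
and `scurve_params(use_paper_ab = TRUE)` is provided to reproduce the
printed curve as written. The exponent is implemented in the shifted form
`e^(−a(s−b))`, consistent with describing `b` as a shift of the curve.

Moves shorter than `2·S1` cannot fit both ramps; they are planned as
symmetric half-ramps re-calibrated to `|S|/2` and flagged degenerate.
Profiles are sampled at 0.1 mm and integrated by trapezoid; the traversal
time floors velocities at `eps·vlmax` so starting from (near) rest takes
finite time. A consequence worth stating: with `eps = 0.01` the dwell near
both ends dominates, and a 0.15 m cycle takes several seconds — feasibility
of a schedule therefore depends strongly on the carriage speed, and
transitions the picker cannot finish before the carriage closes to the
10 mm waiting-zone standoff are flagged as misses (the recognition cadence,
0.7 s between frames, is a second feasibility bound).

```{r motion}
p <- scurve_params()
cyc <- plan_cycle(0, 150, p, V = 0.05)
cyc
integrate_profile(cyc, p)
```

## Trial scoring

`run_trial()` mirrors field-trial accounting. A shoot is *clamped* when its
localization matched a true shoot and its scheduled transition was feasible
— schedule feasibility is the only simulable analog of the mechanical
strip-clamping event. A clamped shoot is *picked* when the cut height lies
within ±3 mm of the true picking point **and** the residual stalk below the
bud base (measured along the stem polyline; the bud base sits one bud
radius below the tip) is non-negative and shorter than 5 mm. Success rates
divide both counts by the total number of shoots and are truncated to one
decimal — that is how such tables are printed (82/98 = 83.67% appears as
83.6, not 83.7). Detection precision/recall/F-score helpers report
undefined ratios as `NA` rather than zero.

```{r trial}
success_rates(98, 90, 82)
detection_metrics(82, 17, 27)
```

## Numerical choices and degenerate inputs

* All randomness flows from explicit seeds; `build_scene()` and
  `render_scene()` restore the caller's RNG state.
* Boxes are half-open `[min, max)` and pixel indices 0-based everywhere in
  the public interface.
* Otsu on a constant image is undefined: `binarize()` warns and returns an
  all-background mask.
* An empty box (no skeleton pixel) is an error in `find_intersection()`
  but a flagged row in `locate_all()` — batch processing reports failures
  rather than dropping them.
* Offsets that run past the fitted row range clamp to it and are flagged.
* Ties in the intersection scan resolve toward the row's median column;
  ties in branch look-ahead resolve by immediate row gain, then heading
  deviation.
* Degenerate generator settings are legitimate: `curvature_amplitude = 0`
  yields perfectly vertical stems (used by the calibration checks), and
  collapsed parameter ranges reproduce exact values.

## Problem sizes used by the checks

The package's own verification runs at desk scale, chosen to finish in
minutes on one CPU: 50 scenes × 3 shoots for the localization-error bound
(the maximum world error over 150 shoots must stay ≤ 3 mm), 200 random
32×32 masks for the thinning properties (each compared bit-for-bit against
a naive re-implementation of the deletion rules), and 0.1 mm sampling for
velocity profiles.

## Known limitations

* The detector is out of scope: boxes come from ground truth or from label
  files; detector error modes (missed or shifted boxes) are exercised only
  via the flagged-failure paths.
* The intersection sits where the *skeleton* branches, which is typically
  1–4 px below the anatomical tip after thinning erodes the bud cap; the
  resulting bias (~0.2–0.8 mm) is part of the measured localization error.
* Thinning erases small isolated symmetric blobs (documented above); no
  spur pruning beyond what the tracer needs is performed.
* The motion model is kinematic only — no motor dynamics, vibration, or
  horizontal-axis control; the carriage speed is exogenous and constant.
* The harvest simulator scores the *accounting* of a field trial on
  synthetic scenes; it does not reproduce physical clamping mechanics.
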
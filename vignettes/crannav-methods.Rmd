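---
title: "Methods: navigated craniosynostosis-surgery analysis with crannav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: navigated craniosynostosis-surgery analysis with crannav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crannav)
```

## The problem

Craniosynostosis — premature fusion of cranial vault sutures in infants —
is corrected by fronto-orbital advancement: the frontal bones and
supraorbital bar are osteotomized, remodeled to a virtually planned target
shape, and fixed back in place. An optical-tracking navigation system can
guide the surgeon in placing the remodeled fragments, provided the
preoperative CT frame is registered to the patient on the table. `crannav`
implements the analysis core of such a workflow: the two-step fiducial
registration with its error bookkeeping, evaluation of navigation accuracy
against an intraoperative surface scan, craniometric outcome metrics, the
mesh post-processing applied to segmented skull models, and a synthetic
phantom generator that lets every stage be tested without patient data.

## Two-step rigid registration

Both registration steps are least-squares rigid point-set fits on
label-matched fiducials (`fit_rigid()`), solved in closed form by the
SVD-based Kabsch/Umeyama method without scale. The determinant sign fix
guarantees a proper rotation (no reflection) even for near-planar fiducial
configurations. Correspondence is always by label: the fiducials are
physically identified points (guide points, pins), so no iterative
closest-point matching exists anywhere in the package.

* The **primary** registration uses six characteristic points on the
  3D-printed osteotomy guides, recorded with a tracked pointer.
* Immediately afterwards, the positions of six resorbable pins drilled
  into healthy bone are recorded once and mapped into the image frame
  through the primary transform (`record_pin_reference()`). This
  image-frame pin set is the fixed reference for the **secondary**
  registration, which is refit from fresh tracker recordings of the pins
  whenever the (non-immobilized) head has moved.

Per fit, the fiducial registration error is reported as
`rmse = sqrt(mean(residuals^2))`. For `N` fiducials with isotropic
localization noise of standard deviation `sigma` per axis, the expected
squared FRE is `3 sigma^2 (1 - 2/N)`; the test suite verifies the solver
against this closed form by Monte Carlo.

Pooling conventions (the published table only prints rounded values, so
the package makes its conventions explicit):

* pooled primary RMSE across cases is the unweighted mean;
* pooled secondary RMSE is the **repetition-count-weighted** mean of the
  per-case means — this is the convention that reproduces the printed
  pooled value from the per-case cells (the unweighted mean does not);
* per-case secondary SD over repetitions uses the sample (n−1) formula;
  pooled SDs are reported in both sample and population conventions
  (via the law of total variance with population within-case variances),
  because the source does not state its convention. Registration
  *duration* is carried as optional metadata only, never computed.

## Navigation accuracy against the surface scan

The intraoperative structured-light scan is treated as the gold standard.
Its pins are identified on the scan (in practice via texture; here they
are supplied as a landmark set), and `register_scan()` maps the scan into
the navigation frame by a pin-based rigid fit. The navigation error of
every recorded bone-surface point is then its unsigned minimum Euclidean
distance to the scanned surface (`point_to_mesh_distance()`), computed
exactly for all point-triangle Voronoi regions (interior, edge, vertex).

The accelerated query prunes triangles by the distance to their
axis-aligned bounding boxes, evaluating exact distances best-first until
the bound exceeds the current minimum; it is bit-equivalent to the
brute-force evaluation over all triangles, which the tests assert at
1e-9 mm. Quartiles of the error distribution use linear interpolation
between order statistics (quantile type 7). Each recorded batch is mapped
into the image frame with the registration that was *in force when it was
recorded* (its stamp), so late secondary registrations never retroactively
"fix" earlier recordings. Because the published per-region errors could
pool points across patients or average per-patient means, the report
emits both.

## Craniometric outcome

Outcome is quantified on three manually selected landmarks: left and
right frontal landmarks (LFL, RFL) and a metopic-suture landmark (MSL).
The interfrontal angle is the angle at MSL between the segments MSL–LFL
and MSL–RFL, computed with `atan2(|u × v|, u·v)` for stability near 0°
and 180°; the transverse forehead width is the LFL–RFL distance. Both are
rigid-transform invariant and symmetric under swapping LFL and RFL.
Outcome error is the absolute plan-vs-postop difference of each metric.
The outcome table flags cases where the postoperative value is below the
planned one for both metrics — the expected signature of planned
overcorrection being reduced intraoperatively — as a reporting flag, not
an assertion.

## Mesh post-processing

Segmented skull surfaces carry stair-step artifact; the package applies
uniform (umbrella-weight) Laplacian smoothing with an explicit Euler step:
each vertex moves toward the average of its edge neighbors by the
relaxation fraction. Defaults are 10 iterations at relaxation 0.1,
matching the stated processing protocol. The exact smoothing variant of
the original toolchain is not documented; the uniform choice is this
package's decision, and boundary vertices are held fixed to avoid
open-edge curl. Hole filling triangulates each boundary loop with a fan
from the loop centroid (one added vertex per hole) — the simplest method
that restores a closed surface; triangulation quality is out of scope.

## The synthetic phantom: a stated world

`make_phantom()` builds a skull surrogate: a scaled, subdivided icosphere
("cranial vault") whose anterior part is clamped against two vertical
wedge planes meeting at the metopic midline, so the forehead dihedral
realizes a controllable interfrontal angle. Anatomical realism is
explicitly not a goal; metric realism is — craniometry and registration
depend only on landmark geometry and surface distances. Constructed
LFL/RFL/MSL landmarks realize the requested angle and width *exactly*;
the postoperative stage realizes the plan minus a specified
undercorrection; guide points are preoperative surface vertices in the
frontal region; pins are posterior surface vertices outside the osteotomy.

Defaults mirror the published operating regime and are fixed once:

* 6 guide points, 6 pins; planned angles near 130–144° with preoperative
  values 20–30° lower; planned widths near 85–98 mm;
* default undercorrection 3.63° and 1.89 mm — the published mean outcome
  errors;
* tracking noise sigma 0.65 mm per axis, chosen because six-fiducial
  RMSE is approximately `sigma * sqrt(2)` (from the expected-FRE² form),
  placing simulated registrations in the reported 0.6–1.3 mm band;
* about ten secondary repetitions with two interleaved head-motion
  events of a few millimetres/degrees, matching the reported 9–17
  repetitions made necessary by head motion;
* 100 recorded points per region (frontal, supraorbital) — the source
  does not state its count; this is a realistic pointer-sampling density
  for the exposed area and gives stable distribution statistics.

`simulate_session()` reproduces the procedure order — primary fit, pin
reference recording, motion/secondary interleaving per schedule, outcome
point recording on the postoperative surface, simulated scan with exact
scan-frame pins — with one deterministic RNG stream per case derived from
the seed. Scan pin identification is simulated noise-free: pin
localization noise already enters through the navigation side, and an
exact scan keeps the noiseless end-to-end recovery property sharp.

What a green test does **not** establish: performance on real anatomy
(soft tissue, partial scan coverage, texture-based pin identification),
non-rigid deformation of remodeled bone, or the patient-specific error
magnitudes of the original surgeries (0.62–0.64 mm means, 0.97 mm third
quartile), which depend on unavailable intraoperative recordings and are
deliberately replaced by property-based checks.

## Numerical choices and edge cases

* Internal coordinates: one right-handed LPS frame in millimetres;
  Slicer-style markup files (RAS) are sign-flipped in x and y on
  read/write, controlled by a flag.
* STL facets are welded at 1e-6 mm so smoothing/hole detection have
  topology; binary STL stores float32, so round-trip tests use a 1e-4
  relative tolerance.
* Collinear fiducial sets are rejected by a singular-value test at
  1e-9 relative; fewer than three label matches is an error naming the
  unmatched labels.
* Degenerate triangles in distance queries are guarded by clamping the
  Gram determinant away from zero; distances stay exact for valid input.
* The pipeline refuses unknown quartile/SD/pooling conventions rather
  than silently defaulting, and reports carry full precision next to
  2-dp display values so rounding questions stay inspectable.

## Known limitations

Pure-R mesh handling targets the phantom scale (thousands of faces);
million-face clinical scans would want compiled acceleration. Hole
filling assumes simple loops; centroid fans can self-intersect on highly
non-convex holes. The wedge phantom has no orbital anatomy, so
"supraorbital" is a band tag, not a true bar.
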
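# crannav

Analysis core of a navigated craniosynostosis-surgery workflow, as an R
package. Craniosynostosis (premature fusion of cranial sutures in
infants) is corrected by fronto-orbital advancement; an optical-tracking
navigation system can verify that the remodeled frontal bone and
supraorbital bar end up where the virtual surgical plan put them.
`crannav` implements the computational pieces of that workflow for
surgeons, biomedical engineers and navigation researchers:

* **Two-step rigid fiducial registration** — closed-form (SVD/Kabsch)
  least-squares fits with per-fiducial residuals and RMSE: a *primary*
  registration on six points of the 3D-printed surgical guides, then a
  repeatable *secondary* registration on six resorbable bone pins that
  compensates head motion, with full session bookkeeping.
* **Navigation-accuracy evaluation** — the intraoperative structured-light
  surface scan is registered to the navigation data via the pins, and the
  navigation error is the unsigned point-to-surface distance of every
  recorded bone point to the scanned mesh (exact point-triangle distances,
  pruned acceleration identical to brute force), summarized as mean ± SD,
  quartiles and maximum per anatomical region.
* **Craniometric outcome** — interfrontal angle at the metopic-suture
  landmark (angle between MSL→LFL and MSL→RFL, stable `atan2` form) and
  transverse forehead width (LFL–RFL distance), with plan-vs-postop
  absolute outcome errors.
* **Mesh post-processing** — uniform Laplacian smoothing (default 10
  iterations, relaxation 0.1) and centroid-fan hole filling for segmented
  skull surfaces; STL/OBJ/CSV/Slicer-markup I/O.
* **Synthetic skull phantom** — a wedge-foreheaded vault whose landmarks
  realize any requested interfrontal angle/width exactly, plus a full
  simulated navigated session (noise, head-motion events, re-registration,
  scan), so the entire pipeline is testable end to end with no patient
  data.

The key relations: a rigid fit minimizes Σ‖R pᵢ + t − qᵢ‖² over proper
rotations (det R = +1); RMSE = √(mean residual²); for N fiducials under
isotropic noise σ the expected squared fiducial error is 3σ²(1 − 2/N);
the interfrontal angle is ∠(LFL − MSL, RFL − MSL).

## Worked example

```r
library(crannav)

spec <- phantom_spec(seed = 11, plan_angle_deg = 130.03, plan_width_mm = 93.28,
                     undercorrection_deg = 6.31, undercorrection_mm = 3.27)
case <- make_phantom(spec)        # meshes + landmarks, exact by construction
sim  <- simulate_session(case)    # primary, pins, 10 secondaries, 2 motions

print(sim$session$primary)
#> primary registration (repetition 1): 6 fiducials, RMSE 0.767 mm

ne <- navigation_error(sim$session, sim$scan, sim$scan_pins)
print(ne$summaries$pooled)
#> pooled: n=200, mean 1.015 +/- 0.640 mm, Q1/median/Q3 0.465/0.952/1.453, max 3.390

plan <- measure_craniometry(case$landmarks_plan, "plan")
post <- measure_craniometry(case$landmarks_postop, "postop")
round(outcome_error(plan, post), 2)
#> angle_error_deg  width_error_mm
#>            6.31            3.27
```

The primary RMSE (0.77 mm) falls in the 0.58–1.25 mm band seen across
real surgeries with the default 0.65 mm tracking noise; the pooled
navigation error is the mean distance of 200 recorded points to the
pin-registered scan; the outcome errors recover the undercorrection the
phantom was built with, exactly.

Case directories (`write_case()`/`read_case()`) and a CLI
(`inst/cli/crannav`, subcommands `simulate`, `register`, `evaluate`,
`morphometry`, `smooth`, `fillholes`, `report`) drive the same pipeline
from files; `run_pipeline()` emits `report.json`, `table1.csv`,
`table2.csv` and a per-point `distances.csv`.

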
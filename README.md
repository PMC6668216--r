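# onhvol

Volumetric analysis of the optic nerve head from radial OCT scans, and its
association with intracranial pressure.

## The problem

Elevated intracranial pressure (ICP) swells the optic nerve head
(papilledema) and deflects peripapillary Bruch's membrane (BM) anteriorly,
toward the vitreous. Both effects are visible on optical coherence
tomography (OCT), but BM is poorly imaged beneath a swollen nerve head, so
naive volumetry is contaminated by segmentation artifact. `onhvol` is for
researchers quantifying these effects from the radial scan pattern: six
B-scans along diameters through the nerve head at 30° increments, each with
segmented internal limiting membrane (ILM) and BM traces and rater-marked BM
opening margins.

From one eye's truncated scan set the package computes, in mm³:

- **ONHV** — optic nerve head volume, the integral of the height
  `h = z_BM − z_ILM` (depth `z` increasing posteriorly, `h` clamped at 0 in
  cup regions) over the disc of truncation radius `R`;
- **BMDV** — BM displacement volume, the *signed* integral of
  `z_BM − z_secant`, the secant being the per-scan line through the
  outermost BM points; `BMDV < 0` means anterior (vitread) bowing, the
  high-ICP morphology;
- **CV** — cup volume below the line joining the ILM points above the
  opening margins.

Integration fills the 12 wedges between adjacent half-scans with 510
trapezoidal prisms each (base area × mean of the four corner heights), under
either a planar-trapezoid (`chord`, flat surface → exactly `3R²h`) or
annular-sector (`sector`, → `πR²h`) base convention. Three BM
representations handle the artifact-prone central 3.2 mm: **traditional**
(chord across the rater-marked opening), **estimated** (chord joining
segmented BM at ±1.6 mm), and **excluded** (central region dropped from
integration). A macular ganglion cell complex volume (3 mm disk around the
fovea) is computed as the atrophy covariate.

Association models mirror standard ophthalmic statistics for paired eyes:
`gee_lm()` fits identity-link generalized estimating equations with an
exchangeable working correlation within subject and robust sandwich standard
errors; `one_eye_lm()` repeats univariable analyses with one eye per subject
(right unless only the left is available) by OLS with Pearson's r.

An analytic phantom module generates synthetic radial scan sets and cohorts
with known ground truth (closed-form / quadrature oracle volumes, linear
generating laws), so the whole pipeline is testable without patient data.

## Worked example

```r
library(onhvol)

# a swollen nerve head with anteriorly bowed BM, as an analytic phantom
p   <- phantom_params(bump_amp_mm = 0.5, bump_sigma_mm = 0.8, bm_bow_mm = -0.1)
eye <- make_radial_phantom(p, subject_id = "demo", eye_id = "OD")
eye
#> <radial_scan_set> subject demo, eye OD: 6 B-scans at 30°, width 5.590 mm (truncated)

compute_volumes(eye, bm_rep("estimated"), base_mode = "chord")
#> <volume_result> demo/OD [estimated BM, chord base]
#>   ONHV 2.0416 mm^3  BMDV -1.0460 mm^3  CV 0.0000 mm^3

phantom_oracle_volumes(p, bm_rep("estimated"), "chord")  # independent truth
#> ONHV 2.0415  BMDV -1.0460  CV 0.0000
```

The 0.5 mm Gaussian swelling integrates to ~2.04 mm³ of nerve head tissue
(chord base), the 0.1 mm anterior bow to −1.05 mm³ of displacement — the
wedge integrator agrees with the solid-of-revolution oracle to 4 decimal
places — and a bowed-but-uncupped ILM gives zero cup volume.

```r
tab <- simulate_cohort(cohort_params(n_subjects = 200, seed = 42))
summary(gee_lm(onhv_mm3 ~ icp_cmH2O, tab))
#> Linear GEE (exchangeable working correlation), robust SEs
#> 348 eyes in 200 subjects; scale 0.3561; within-subject correlation 0.742
#>
#>             Estimate Robust SE         95% CI      p
#> (Intercept)   4.6054   0.10459 (4.400, 4.810) <2e-16
#> icp_cmH2O     0.1348   0.00296 (0.129, 0.141) <2e-16
```

The fitted ICP coefficient, 0.135 mm³ per cm H₂O, recovers the simulator's
generating slope (0.136) well inside its robust CI, with the within-subject
correlation from the shared subject effect estimated at 0.74.

A command-line surface wraps the same functions
(`inst/exec/onhv volumes|phantom|cohort|associate ...`); see `?onhv_cli`.

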
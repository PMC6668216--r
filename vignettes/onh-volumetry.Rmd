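---
title: "Radial-scan optic nerve head volumetry: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial-scan optic nerve head volumetry: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onhvol)
```

## The measurement problem

Papilledema — swelling of the optic nerve head under elevated intracranial
pressure (ICP) — and the accompanying anterior deflection of peripapillary
Bruch's membrane (BM) are both visible on optical coherence tomography (OCT).
`onhvol` turns segmented radial OCT B-scans of the optic nerve head into three
volumes:

* **ONHV** (optic nerve head volume): tissue between the internal limiting
  membrane (ILM) and a continuous BM boundary, with cup regions excluded;
* **BMDV** (BM displacement volume): the *signed* volume between BM and a
  per-scan secant line through the outermost BM points — negative values mean
  the membrane is bowed anteriorly, toward the vitreous, the morphology of
  high ICP;
* **CV** (cup volume): the central ILM depression below the line joining the
  ILM points immediately above the BM opening margins.

The input geometry is six B-scans along diameters through the nerve head at
30° increments. Splitting each scan at its center gives 12 half-scans at 30°
azimuthal spacing, and the surface between adjacent half-scans is filled with
trapezoidal prisms.

## Depth and coordinate conventions

Depth `z` increases posteriorly (the OCT A-scan direction), so the ILM has
smaller depth than BM wherever tissue is present, and optic nerve height is
the positive difference `BM − ILM`. "Anterior"/"vitread" means smaller `z`.
All file formats store depths in pixels with explicit µm/pixel scales; every
public quantity is in mm or mm³.

The optic nerve head center is taken as the midpoint of each truncated scan,
and all six scans are assumed concentric there. Scans are truncated
symmetrically about that midpoint to a common width — by default the width of
the shortest scan in the sample (`truncate_scan_set()`); a fixed width can be
forced for cross-sample comparability. Because samples are discrete, the
retained samples of a wider scan can stop up to half a pixel (~5 µm) short of
the exact common half-width; radial resampling covers that sub-pixel gap by
constant (edge-value) extrapolation, a bias far below every tolerance used
here.

## The three Bruch's membrane representations

Laser penetration through a swollen nerve head is poor, so segmented BM under
the nerve head is unreliable. Three representations of the continuous BM
boundary are provided (`bm_rep()`):

* **traditional** — segmented BM with a straight chord bridging the
  rater-marked opening margins;
* **estimated** — segmented BM outside a central region of half-width
  `central_half_width_mm` (default 1.6 mm, i.e. a 3.2 mm region, the maximum
  BM opening extent seen across scans; in a new sample this knob should be
  re-set to that sample's maximum opening), with a chord joining the
  segmented BM interpolated at exactly ±1.6 mm inside it;
* **excluded** — segmented BM outside the central region, and no contribution
  at all from radii inside it: prisms with any corner at `r < 1.6` mm are
  dropped from ONHV and BMDV.

The secant for BMDV always joins the segmented BM at the two truncation
edges, for every representation — one secant per B-scan, independent of how
the central region is handled. CV always uses the opening-margin geometry and
is representation-independent.

## Discretization and the prism formula

Each half-scan is resampled by linear interpolation onto a uniform radial
grid of `n_intervals + 1` nodes from the center to the truncation radius
`R`; the default `n_intervals = 510` matches the discretization of the
original description (510 prisms per wedge, 12 wedges). Each prism's volume
is its base area times the mean of its four corner heights — the natural
bilinear-consistent choice; the source description does not fix how the four
corners combine.

Two base-area conventions are implemented because the geometric figure filled
between two rays 30° apart is genuinely ambiguous:

* `chord` (default): the planar trapezoid between the bounding rays, area
  `(r₂² − r₁²)·sin 15°·cos 15°`. A constant height `h` then integrates to the
  inscribed-dodecagon prism, exactly `3R²h`.
* `sector`: the annular sector, `(π/12)(r₂² − r₁²)`. Constant height
  integrates exactly to `πR²h` (the radial sum telescopes).

For smooth surfaces the two differ by the fixed factor `3/π ≈ 0.955`.
Neither is asserted to be the convention of the original software; reported
results should state the mode, and `compute_volumes()` records it.

Signed surfaces (BMDV) enter the prism mean with sign and are never clamped.
The ONHV height is clamped at zero wherever the ILM dips posterior to the BM
boundary (the cup), which makes ONHV invariant to pre-clamping the ILM at the
boundary — a property the test suite checks directly.

## The analytic phantom

`phantom_params()` defines a radially symmetric eye from closed-form
surfaces: a flat BM reference at `baseline_z_mm` with a quadratic bow
`β(1 − (r/R)²)` (positive β = posterior), an ILM raised above BM by a
Gaussian bump `A·exp(−r²/2σ²)` (nerve head swelling) plus an optional central
parabolic cup dip, and an unsegmented BM gap of half-width
`opening_radius_mm`. Defaults (R = 2.795 mm, i.e. the 5.59 mm truncated
width; opening half-width 0.75 mm; A = 0.5 mm, σ = 0.8 mm; 1024 samples per
scan, axial scale 3.87 µm/px) are realistic for nerve-head OCT of a swollen
disc.

Because the phantom is radially symmetric, every representation-specific
height profile has a one-dimensional solid-of-revolution integral
`2π∫ r·h(r) dr` that `phantom_oracle_volumes()` evaluates by adaptive
quadrature (independently of the wedge integrator), times `3/π` in chord
mode. The test suite requires the full pipeline to agree with this oracle to
better than 1% at the default grid for all three volumes, all three
representations and both base modes — and against pure closed forms
(Gaussian-bump ONHV, quadratic-bow BMDV) when the opening is negligible.
The oracle is also what `calibrate_bump_amplitude()` inverts (exactly, since
the unclamped integral is affine in the amplitude).

What the phantom does *not* emulate: speckle, segmentation error (beyond
what a user injects through the asymmetry hook), decentered scans, and
non-radially-symmetric pathology (the `ilm_asym` hook exists for asymmetry
experiments, but the 1-D oracle then refuses to run). Passing the oracle
tests therefore validates the geometry and numerics of the integrator, not
robustness to real segmentation noise.

One directional subtlety is worth recording: with *anterior* central bowing
(β < 0, the high-ICP shape) the opening chord anchors at progressively deeper
margin points as the rater-marked opening widens, so traditional ONHV grows
monotonically with the opening radius — the quantitative face of the concern
that apparent BM-opening widening inflates traditional measurements. With
posterior bowing the effect reverses; the test suite pins the anterior case.

## Cohort simulation and the association models

`simulate_cohort()` draws per-subject ICP uniformly on 10–55 cm H₂O (the
clinically sampled range), a per-outcome subject random intercept
(sd `sd_subject_mm3`, default 0.5 mm³), and eye-level residuals
(`sd_eye_mm3`, default 0.3 mm³); each eye's volume follows
`intercept + slope·ICP (+ gcc_coef·GCCV)`. Default intercepts/slopes
(ONHV 4.606 + 0.136·ICP; BMDV 2.100 − 0.038·ICP mm³) are realistic
traditional-representation values; GCCV is N(0.65, 0.07²) mm³, a plausible
3-mm-disk ganglion cell complex volume. The subject/eye noise scales are set
for test power rather than to mimic any clinical covariance estimate, and the
same scales apply to each outcome; between-eye correlation beyond the shared
subject intercept is not modeled. Roughly a quarter of subjects contribute a
single eye (`p_both_eyes = 0.76`), mirroring realistic exclusion rates from
incomplete imaging.

`gee_lm()` fits the marginal linear model by generalized estimating
equations: identity link, exchangeable working correlation across the eyes of
a subject (independence available for sensitivity), robust sandwich
covariance, Wald normal-theory 95% CIs and p-values with no small-sample
correction. The implementation is in-package, and is cross-checked in the
tests against the OLS + cluster-sandwich route (`sandwich::vcovCL`) for the
independence structure, against noiseless cohorts (exact recovery), and in a
Monte-Carlo coverage experiment (100 cohorts of 500 subjects; ≥ 93 of the
nominal-95% CIs must cover the generating slope — at much smaller cluster
counts the uncorrected sandwich is expected to undercover slightly).
`one_eye_lm()` repeats univariable analyses with one eye per subject (right
eye unless only the left is available) by ordinary least squares with
t-based CIs, reporting Pearson's r signed by the slope;
`pairwise_correlation()` gives plain Pearson correlations. No
multiple-testing adjustment is applied anywhere.

## Numerical choices and degenerate inputs

* Interpolation is linear everywhere (boundaries between samples, half-scan
  resampling); validity masks are geometric (a node is invalid iff its radius
  lies strictly inside the excluded region) so the excluded representation's
  footprint is exact on the grid.
* Rater disagreement uses a strict `> threshold` rule; a difference of
  exactly 2 pixels is not flagged.
* GCC disk volume uses pixel-center-in-circle inclusion; its error against
  the analytic cylinder scales with pixel area, so comparisons use fine
  grids.
* Zero-noise model fits produce zero residuals; the exchangeable correlation
  estimate is then defined as 0 and robust SEs collapse to 0 (p-values 0 for
  nonzero coefficients).
* Margins must survive truncation, BM must exist at both truncation edges
  (for the secant) and at ±1.6 mm (for the estimated representation);
  violations are errors, not silent repairs.

## Problem sizes used in the validation suite

The shipped tests run phantoms at 301–1024 samples per scan with the default
510-interval grid, cohorts up to 2000 subjects, 50-seed bias and 100-seed
coverage experiments at 500 subjects, all chosen as the smallest sizes at
which the Monte-Carlo noise floor sits comfortably below the asserted
tolerances.

## Known limitations

* No automated segmentation, no proprietary device-format ingestion: the
  package starts from segmented traces in the documented JSON format.
* The concentric-scan assumption ignores scan decentration; real radial sets
  with eccentric centers would need registration upstream.
* The chord/sector ambiguity is a systematic ≈4.5% scale choice that must be
  reported alongside any volume.
* BMDV in the excluded representation keeps the truncation-edge secant; an
  alternative reading (recomputing the secant from retained BM only) is not
  implemented.
* Published clinical coefficient tables from specific cohorts depend on the
  original 30 eyes and SPSS's GEE details (scale estimation, CI method);
  numerical equality with any published CI is not claimed. What the package
  guarantees is structural: exact recovery of noiseless generating laws and
  unbiased slope recovery under the simulator's study conditions.
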
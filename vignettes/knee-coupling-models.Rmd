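---
title: "Polynomial coupling models of knee kinematics: methods and design"
author: "kneekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polynomial coupling models of knee kinematics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneekin)
```

## The modelling problem

Twelve kinematic parameters describe the complete three-dimensional motion
of the knee-joint complex: six at the tibiofemoral (TF) joint — lateral
shift, anterior drawer, joint distraction (mm) and flexion, abduction,
external rotation (deg) — and six at the patellofemoral (PF) joint —
lateral shift, anterior translation, superior translation (mm) and flexion,
lateral rotation, lateral tilt (deg). Ligaments, capsule and articular
contact couple these motions: most of them track the TF flexion angle
closely, while external tibial rotation is only weakly related to flexion.

`kneekin` models this coupling with per-output polynomials in a small set
of input rotations. An *n*-DOF model takes *n* TF parameters as inputs
(always including flexion, the primary motion) and expresses each remaining
parameter *y* as

$$ y = c_0 + \sum_{i=1}^{n}\sum_{k=1}^{d} c_{ki}\, x_i^k , $$

with no cross terms — for the quadratic 2-DOF model in flexion $f$ and
external rotation $e$ this is $y = c_0 + c_{11} f + c_{12} e + c_{21} f^2 +
c_{22} e^2$. Inputs are never modelled; prediction passes them through
unchanged, so their prediction error is identically zero. Two packaged
reference models (`knee_package_model("table1_1dof")`, `"table1_2dof"`)
ship with the package, with coefficients stored as decimal strings so they
serialize digit-for-digit. All angles are **degrees** throughout; radian
inputs would silently produce wrong predictions.

## Fitting and residual metrics

`knee_fit()` pools all observations of a cohort with equal weight (each
participant-activity trial contributes its resampled time points) and
solves one ordinary least-squares problem per output through a QR
factorization of the shared design matrix. The normal equations are never
formed; a rank-deficient design — e.g. a constant input channel — is a hard
error rather than a silent pseudo-inverse fit. Coefficients are estimated
in raw degree/millimetre units without centering or standardization so that
fitted models are directly comparable with the packaged ones; the
orthogonal factorization carries the conditioning burden this creates at
quadratic order.

Goodness of fit is summarized per joint: the TF residual pools the
predicted TF parameters as
$\mathrm{RMSR_{TFJ}} = \sqrt{\frac{1}{(6-n)p}\sum_i\sum_j (y_{ij}-y'_{ij})^2}$
over the $6-n$ outputs and $p$ observations, and the PF residual uses the
analogous expression over all six PF parameters. A rotation error of 1 deg
and a translation error of 1 mm are weighted equally, written deg|mm.

Model selection is supported by two sweeps. `enumerate_input_sets()` fits
every subset of the six TF parameters that contains flexion (6 candidates
up to 2-DOF, 31 up to 5-DOF) and scores each on the training pool;
`order_sweep()` varies the polynomial degree at a fixed input set. Both
report training residuals, which are non-increasing under basis nesting —
the sweeps show where added complexity stops paying, not out-of-sample
accuracy.

## Cross-validation and report conventions

`knee_loocv()` treats the participant as the unit of exchangeability:
each fold fits on all other participants' pooled trials and predicts the
left-out participant from their measured input channels. Three reporting
conventions are fixed here and used everywhere:

* a participant's per-parameter RMSE pools raw squared errors over all of
  their activities before the square root (with equal counts this equals
  the RMS of per-activity RMSEs);
* the pooled "All" value per joint panel is the RMS over *predicted*
  parameters only — input parameters, which are zero-error by
  construction, are excluded so they cannot deflate the summary;
* the "Mean" column is the arithmetic mean of the per-participant values,
  not a pooled RMS.

A fold whose training design is rank-deficient is recorded as a fold-level
error in the report rather than silently propagating `NaN`.

## Preprocessing chain

Raw trials are conditioned in the order filter → resample → scale, because
the filter needs uniform sampling in true time:

* **Filtering.** Fourth-order low-pass Butterworth, 10 Hz cut-off at
  200 Hz sampling (all configurable via `knee_preprocess_config()`). The
  filter is run forward and backward for zero phase lag — the standard
  choice in gait analysis, where phase distortion of kinematic landmarks
  matters more than the steeper effective roll-off. Each pass starts from
  the step-response steady state scaled to the first sample, and the
  series is extended by reflected padding of length three times the filter
  order, so constant signals pass through exactly and endpoints are not
  contaminated by start-up transients. Trials no longer than the padding
  length are rejected.
* **Time normalization.** Natural cubic-spline resampling onto 201 evenly
  spaced points of normalized time (linear for trials with fewer than 4
  samples). Endpoints are preserved exactly and affine signals are
  reproduced exactly.
* **Translation scaling.** The six translation channels are multiplied by
  `reference_width / bicondylar_width` (reference 81.7 mm, a cohort-mean
  femoral bicondylar width), i.e. expressed on a reference-width knee so
  translations are comparable across participants. The direction of this
  normalization is a documented choice — the operation is exactly
  invertible (`invert = TRUE`) if the opposite convention is wanted.
  Rotations are untouched.

## Anatomical frames and the joint coordinate system

Bone frames are constructed from surface geometry the way the packaged
models' coordinate systems are defined: the femoral X axis is the axis of
an orthogonal-distance least-squares cylinder fitted to the
posterior/distal condylar surface, the femoral long axis comes from a cone
fitted to the diaphysis, Y = normalize(L1 × X), Z = X × Y, and the origin
is the foot of the perpendicular from the intercondylar notch apex onto
the cylinder axis. The tibial Z axis follows the tibial diaphyseal cone
through the eminence midpoint, with the origin placed on that axis at the
level of the femoral origin (hence dependent on the reference pose
supplied); the patellar Y axis is the largest-moment principal axis of
inertia with X set by the posterior ridge direction. Surface fits are
Levenberg–Marquardt iterations initialized from principal-component axes
(converged when the parameter step falls below 1e-10, with a 200-iteration
cap that errors rather than returning a stale estimate); degenerate
inputs — coplanar points, parallel axes, spherically symmetric inertia —
are hard errors.

Relative bone pose is parameterized Grood–Suntay style: rotations about
the parent-fixed X axis (flexion), the child-fixed Z axis (axial
rotation), and the mutually perpendicular floating axis (abduction, equal
to the angle between the fixed axes minus 90 deg). Algebraically this is a
Cardan X-Y-Z factorization of the relative rotation. Translations are the
components of the parent-to-child origin vector *in the (non-orthogonal)
basis* of the two fixed axes and the floating axis — the basis
decomposition rather than three oblique projections, chosen so that
`jcs_compose()` and `jcs_decompose()` are exact mutual inverses. Published
figures encode per-parameter sign arrows that are not recoverable from
text alone, so signs live in `jcs_spec()` with defaults plausible for a
right knee (lateral, anterior, proximal, flexion, abduction and external
rotation positive); left knees should be mirrored before decomposition.
Poses within 0.1 deg of gimbal lock (fixed axes parallel) are rejected.
`reexpress_trajectory()` conjugates each sample's relative pose with
constant per-bone frame offsets, the generic mechanism for moving a model
to a differently defined coordinate system.

## The synthetic cohort generator

No public accession exists for multi-activity biplane X-ray knee
kinematics, so `simulate_cohort()` generates cohorts with known ground
truth. Its defaults emulate the study conditions the packaged models come
from: 10 participants × 6 activities × 201 time points, bicondylar widths
drawn around 81.7 mm, channel noise of 0.5 deg|mm (commensurate with
reported biplane X-ray accuracy bounds of ~0.8 mm/deg at the TF joint),
participant-level coefficient variation of 10% (multiplicative,
`1 + N(0, 0.1)` per coefficient), and an external-rotation signal whose
squared correlation with flexion is 0.3 — "weak" coupling, implemented by
mixing a standardized flexion component with an orthogonalized smooth
independent component so the per-trial R² equals the coupling parameter
exactly. Flexion profiles are stylized per activity (open-chain: a smooth
0→100 deg sweep; gait: a small stance bump plus a large swing bump peaking
below ~85 deg); they are fixtures with realistic ranges and smoothness,
not claims about real waveforms.

Two deliberate idealizations: noise is i.i.d. Gaussian per channel with no
temporal correlation, and it is added to *output* channels only. Input
channels stay clean because they are the signals that drive the model;
this keeps the closed-form OLS sampling covariance $\sigma^2(X^TX)^{-1}$
exact, which is what the parameter-recovery tests check against. Real
measured inputs carry noise too, so real-data fits face an
errors-in-variables attenuation these tests do not exercise. Likewise,
passing tests on synthetic cohorts show correctness of the machinery — not
that a quadratic polynomial is an adequate model of any particular knee.

Randomness is reproducible and order-independent: one global seed expands
into per-participant and per-trial substreams through a counter-based
derivation, so adding participants or activities never changes earlier
draws. `sample_bone_surfaces()` plays the same role for the anatomy
module: parametric condylar-cylinder, diaphyseal-cone and patellar
ellipsoid patches (the ellipsoid sampled on a symmetric grid so its
inertia axes are exact), with landmarks and the implied ground-truth
frames recorded, optional isotropic point noise, and an optional rigid
motion for equivariance checks.

## Numerical and design notes

* Packaged coefficients are stored and round-tripped as decimal strings;
  fitted coefficients serialize via `%.17g`, restoring to within 1 ulp.
* Report values are rounded to 1 decimal only at the presentation layer
  (`write_cv(digits = 1)`); everything internal is full precision.
* The test suite and examples use reduced problem sizes (2–3 participants,
  51-point trials) where the property under test does not require the full
  study scale; parameter-recovery checks run once at the full
  10 × 6 × 201 scale.
* Known limitations: no regularized, hierarchical or spline fits (by
  design — the model class is the contribution being packaged); no gap
  filling, trials must be complete; no image processing or automatic
  landmark detection, landmarks are inputs; cross-term polynomial bases
  are intentionally out of scope.
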
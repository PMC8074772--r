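---
title: "Markerless centre-of-mass reconstruction: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless centre-of-mass reconstruction: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(com3d)
```

## The problem

CNN pose estimators such as OpenPose return, per camera and per frame, 25
2D body landmarks with confidences — but no cross-camera association, no
3D, and a characteristic error budget: high-frequency keypoint jitter,
occasional gross mislocalisations, contralateral switching of entire
limbs, and missing detections. `com3d` turns those per-view detections
into whole-body centre-of-mass (CoM) position and velocity in a metric
world frame, and quantifies how well the result agrees with a criterion
(e.g. marker-based) signal. Differentiation amplifies jitter, so the
package's central comparison is between three treatments of the 3D
joint-centre trajectories: no filtering, a zero-lag Butterworth low-pass,
and a fixed-interval Kalman (RTS) smoother.

## The pipeline model, stage by stage

**Camera model.** Each camera is a pinhole with the standard
5-coefficient radial–tangential distortion model (`k1,k2,k3,p1,p2`),
applied in normalized coordinates before the intrinsic mapping. The
rotation is world-to-camera; the world frame is z-up with x along the
running direction. Back-projection undistorts by fixed-point iteration
(convergence 1e-12 in normalized units, capped at 100 iterations — strong
radial distortion near the field edge converges slowly, and 20 iterations
proved insufficient at |k1| ≈ 0.15).

**Association.** All detections of a person in one view are reduced to
the componentwise median of their valid keypoints — a compact, outlier-
resistant person location. The tracked footprint is divided into vertical
columns on a ground-plane grid (cell 0.25 m, height 0–2.2 m, covering
crouched through upright poses; these values are configurable because no
canonical choice exists). Each column projects into each camera as the
axis-aligned bounding box of its eight corners; a column's occupancy
score is `o_k = m_k / v_k`, containing views over visible views, with
columns visible in fewer than 2 views excluded (a 3D point needs two rays
regardless). People are the local maxima of the score map at `o_k >= 0.5`
with 0.5 m non-maximum suppression; the median points that contributed to
a peak's column define the cross-camera group, each view contributing at
most one detection and ties resolving deterministically (higher score
first, then grid index). Frame-to-frame identity is kept by
nearest-ground-position linking — deliberately simple plumbing, since
association is per frame.

**Triangulation.** Each keypoint's detections back-project to rays; the
3D position is the point minimizing the sum of squared perpendicular ray
distances. Because a single swapped limb or mislocalised joint in one
view would otherwise drag the least-squares solution, a RANSAC step first
proposes two-ray intersections (all pairs, enumerated exhaustively up to
8 rays and beyond while the pair count stays within the iteration budget)
and keeps the proposal consistent with the most rays; the final point is
the least-squares intersection of that consensus set. The inlier
threshold defaults to 0.04 m, the order of reported markerless
joint-centre error; features with fewer than two consistent rays are
marked missing rather than fabricated.

**Smoothing.** Both treatments are applied identically to every 3D
coordinate channel before CoM computation.

* *Butterworth*: 4th order, dual-pass (forward–backward), so zero phase —
  the biomechanics convention; no dual-pass cutoff correction is applied,
  so the quoted cutoff is the per-pass design cutoff. The default cutoff
  is 12 Hz. End effects are handled by odd-reflection padding with the
  endpoint value subtracted before filtering, which removes the zero-state
  step transient (the padded length is `2 * order * ceiling(rate/cutoff)`
  samples). Gaps are linearly interpolated first and flagged — an IIR
  filter cannot skip samples.
* *Cutoff selection*: for each candidate cutoff the residual
  (raw − filtered) is scored by the sum of squared autocorrelations at
  lags 1–20; an appropriately chosen cutoff leaves a residual that looks
  like white noise, whose autocorrelation is zero at all non-zero lags.
  Residuals below 1e-12 of the signal variance carry no whiteness
  information and score zero, and exact ties resolve to the lowest
  cutoff. Two boundary behaviours are worth knowing: on pure white noise
  the selection sits at the low end of the grid (everything is residual,
  and the residual is whitest when the filter removes least), and on a
  noiseless band-limited signal it picks the lowest cutoff whose residual
  is numerically zero.
* *Kalman*: per-channel constant-velocity state with white-noise
  acceleration (a constant-acceleration model is available), forward
  filter plus backward Rauch–Tung–Striebel recursion. Missing samples are
  skipped measurement updates, so reconstruction gaps need no
  interpolation and emerge with honestly inflated posterior variance.
  Hyperparameters `q` (process noise intensity, m²/s³) and `r`
  (measurement noise variance, m²) are tuned by grid search with masked
  k-fold cross-validation (every k-th sample held out, fold offsets
  shuffled from the seed, RMSE at masked samples). One structural fact
  matters when reading tuning output: in steady state the smoother gains
  depend on `q/r` only, so the CV score surface has a flat ridge along
  constant `q/r` and the *ratio* (equivalently the smoother bandwidth) is
  what the data identify; ties resolve to the lower `q`, then lower `r`.
  The package default `q = 20, r = 2e-4` is the ratio selected by this
  tuner on the default synthetic scene (about 2.8 Hz bandwidth), with `r`
  pinned at the observed triangulated keypoint noise level (~14 mm SD).

**CoM model.** Whole-body CoM is the mass-fraction-weighted sum of
segment CoMs, each at a fixed longitudinal ratio between its endpoints,
using de Leva's (1996) adjusted sex-specific parameters. body_25 offers
no vertex, suprasternale or hand landmarks, so the mapping is a documented
package convention, not a reproduction of any marker-based model: trunk
Neck→MidHip, head Neck→Nose, hands as point masses at the wrists, foot
Heel→BigToe. Mass fractions are renormalised to sum to exactly 1, making
the CoM a convex combination of joint positions (hence translation- and
rotation-equivariant and always inside the keypoint hull). Velocities are
second-order central differences; the two endpoint samples use one-sided
stencils and are flagged, and any gap inside a stencil leaves the
velocity undefined rather than silently interpolated.

**Validity checks.** Two physical checks are built in: a rigid two-marker
wand of known length (default 601.4 mm) tracked through the volume, whose
reconstructed inter-marker distance exposes scale error; and the
flight-phase check, which fits a quadratic to the vertical CoM trajectory
of an airborne segment and compares its constant second derivative with
−9.81 m/s². The simulator's gravity constant is exactly 9.81 m/s² so the
noiseless check is exact.

**Agreement.** Bland–Altman bias, SD of the differences (n−1), and 95%
limits of agreement `bias ± 1.96·SD` (classical multiplier, not a
t-quantile), plus ordinary least-squares regression of the markerless
series on the criterion with `R² = 1 − SS_res/SS_tot`. Differences are
pooled across frames per treatment and component; the comparison table
has one row per (treatment, component) rounded to 3 decimals on output.

## The synthetic scene: what it emulates and what it does not

The generator builds a ring of frame-locked cameras (default nine,
1920×1080, ~1000 px focal length — a ~6 mm lens with ~90° field of view
at that resolution — at 200 Hz, mild k1 = −0.05 distortion) around a
capture volume, and an articulated 25-keypoint body with four profiles:
*sprint* (sinusoidal limb oscillation at a 2 Hz stride superposed on a
5 m/s + 2 m/s² forward ramp), *push* (the same gait crouched, torso
pitched ~57°, lower and slower), *ballistic* (a frozen pose on an exact
projectile path — the vertical CoM channel is exactly quadratic by
construction), and *static*. Limb swing leaves a sub-1% oscillation on
the sprint CoM velocity ramp; the ramp is monotone to within that
residual, not exactly.

Rendering projects every keypoint into every camera and applies, in
order: dropout (plus out-of-view culling), Gaussian pixel jitter, gross
outliers, and whole-leg left/right switching per frame and view.
Default magnitudes — jitter 3 px, outliers 2% at 150 px, swaps 5% of
frame-views, dropout 5% — were chosen once so that the *unfiltered*
horizontal CoM-velocity error SD lands at the order of 1 m/s, the scale
at which the smoothing comparison is scientifically meaningful; this is
calibration by construction, not a reproduction of any measured error
budget. All randomness flows from one seed; identical seeds give
bit-identical scenes.

What the generator does **not** model: confidence values carry no
information (uniform draws), whereas real estimator confidences correlate
with error; jitter is white and isotropic, whereas real jitter is
temporally structured; outliers are unbiased displacements rather than
semantically confusable structures (the floor, other people's limbs); and
the articulated body is kinematically smooth with constant segment
lengths. Passing the package's tests therefore demonstrates correctness
of the *pipeline machinery* under a controlled error model — it does not
certify accuracy on real footage, where the 2D estimator's biases
dominate.

## Numerical choices

* Ray-to-point distances use the explicit residual vector
  `q − (q·d)d`; the algebraically equal `‖q‖² − (q·d)²` form loses ~8
  significant digits to cancellation at metre-scale camera offsets.
* The per-feature least-squares intersection solves its symmetric 3×3
  normal equations in closed form (cofactors), vectorized across all
  features of all frames; systems with |det| < 1e-12 are treated as
  degenerate and the feature is dropped.
* Rays are declared parallel (degenerate) when the normal matrix's
  smallest eigenvalue falls below 1e-9·n; two-ray proposals are skipped
  when `1 − (d₁·d₂)² < 1e-12`.
* Rigid alignment is Kabsch (SVD with a determinant sign correction);
  scale is excluded by default because both systems are metrically
  calibrated, with a similarity variant behind a flag. Collinearity is
  rejected at a 1e-9 relative singular-value threshold.
* Keypoint JSON is written with 17 significant digits so that
  write/read round-trips are bit-exact.

## Problem sizes used by the validation suite

The test suite and acceptance checks run entirely on synthetic scenes
generated in code: the end-to-end noiseless identity uses a 9-camera,
0.3 s scene; the treatment-ordering property uses the full default scene
(nine cameras, 1.5 s at 200 Hz, default noise) over 100 seeds; tuner
recovery uses 10 seeds of a 300-sample constant-velocity process; the
wand check uses 100 frames in a 6-camera rig. These sizes were chosen as
the smallest at which each property is stable across seeds.

## Known limitations

* Association assumes people occupy separate ground columns; two bodies
  within ~one cell of each other can merge into one peak (real
  occupancy-map systems share this failure mode).
* The hand is a point mass at the wrist; during vigorous arm swing this
  slightly misplaces the arm segment CoM.
* Track linking is nearest-neighbour with a 1 m radius — adequate for a
  handful of well-separated athletes, not a crowd tracker.
* The Kalman smoother is linear-Gaussian; it is more robust to isolated
  outliers than the Butterworth filter only because RANSAC already
  removed most of them and its bandwidth is narrower, not because it is
  a robust estimator.

## A minimal worked example

```{r example, fig.width = 6, fig.height = 4}
cfg <- scene_config(n_cameras = 6, duration = 0.5, seed = 42)
rig <- make_rig(cfg)
motion <- simulate_motion(cfg)
detections <- render_detections(motion, rig, noise_model(), seed = 42)
result <- com_pipeline(detections, rig, rate = cfg$rate,
                       criterion_com = motion$com)
summary(result)
plot(result, component = "horizontal", what = "velocity")
```
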
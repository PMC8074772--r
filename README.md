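# com3d — markerless multi-camera centre-of-mass reconstruction

`com3d` is an R package for sports biomechanists and computer-vision
practitioners who want whole-body centre-of-mass (CoM) position and
velocity from multi-camera 2D human pose estimates — without markers.
It consumes per-camera OpenPose body_25 keypoint files plus a camera
calibration set, and produces 3D joint-centre trajectories, CoM
kinematics under three denoising treatments, and agreement statistics
against a criterion (e.g. marker-based) signal.

## What it computes

1. **Association** — person detections are grouped across views with a
   ground-plane *occupancy map*: each person reduces to the median point
   p(i,v) of their valid keypoints; each vertical grid column k scores
   o_k = m_k / v_k (views whose projected column bounding box contains a
   median point, over views where the column is visible); peaks of the
   score map are people.
2. **Triangulation** — each detection d(i,v) back-projects through the
   calibration P_v to a ray r_v = P_v(d(i,v)); a RANSAC over two-ray
   proposals selects the consensus ray set, and the joint centre is the
   least-squares "intersection" (closest point to all inlier rays).
3. **Smoothing** — the 3D channels are treated three ways: unfiltered;
   zero-lag 4th-order Butterworth (default cutoff 12 Hz, or selected by
   residual-autocorrelation whiteness); fixed-interval Kalman (RTS)
   smoother with grid-search + cross-validated (q, r).
4. **CoM kinematics** — CoM = Σ_s m_s (p_s + c_s (d_s − p_s)) over de
   Leva segment parameters mapped to body_25 landmarks; velocities by
   central differences; a flight-phase check fits a quadratic to the
   airborne vertical CoM and compares its second derivative with
   −9.81 m·s⁻².
5. **Agreement** — Bland–Altman (bias, SD, 95% limits of agreement
   bias ± 1.96 SD) and linear regression (R²), one row per treatment and
   component.

A fully ground-truthed synthetic scene generator (9-camera ring,
1920×1080, 200 Hz, gait-like articulated motion, and the characteristic
pose-estimator noise modes: keypoint jitter, gross outliers,
contralateral limb switching, dropouts) makes every stage testable with
no capture hardware.

## A worked example

```r
library(com3d)

cfg <- scene_config(n_cameras = 6, duration = 0.5, seed = 42)
rig <- make_rig(cfg)
motion <- simulate_motion(cfg)                       # ground truth
detections <- render_detections(motion, rig, noise_model(), seed = 42)

result <- com_pipeline(detections, rig, rate = cfg$rate,
                       criterion_com = motion$com)
summary(result)
```

which prints (abridged to the velocity table):

```
<com_pipeline: 100 frames @ 200 Hz, 1 track(s), treatments: raw, lowpass, kalman>
  detections in: 600; groups: 100; 3D features: 2500; gaps: 0

CoM velocity agreement (markerless - criterion):
  treatment  component     bias     sd loa_low loa_high r_squared  n
1       raw horizontal 0.010989 1.1395  -2.222    2.244    0.0832 98
2       raw   vertical 0.012156 0.6925  -1.345    1.369    0.4565 98
3   lowpass horizontal 0.005448 0.0844  -0.160    0.171    0.9360 98
4   lowpass   vertical 0.010294 0.0995  -0.185    0.205    0.9777 98
5    kalman horizontal 0.006652 0.0803  -0.151    0.164    0.9463 98
6    kalman   vertical 0.000936 0.0687  -0.134    0.136    0.9875 98
```

Read it as: differentiating raw pose estimates leaves ~1 m/s of velocity
noise (R² 0.08 against the criterion); both smoothing treatments cut the
error by an order of magnitude, the Kalman smoother doing best, and the
bias stays near zero throughout. (`plot(result)` overlays the three
treatments' velocity traces.)

File-based runs use `run_pipeline("config.yaml")` or the thin CLI at
`inst/cli/com3d` (`com3d simulate`, `com3d run --config …`,
`com3d agree`); formats are consolidated per-camera OpenPose JSON (native
one-file-per-frame directories are also read), a YAML calibration set,
and CSV trajectory tables. The world frame is z-up, x along the running
direction.

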
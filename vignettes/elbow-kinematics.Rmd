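---
title: "From wearable sensor streams to elbow kinematics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wearable sensor streams to elbow kinematics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(elbowkin)
```

## The problem

Two inertial–magnetic sensor units are strapped to the arm and the forearm.
Each streams nine channels — tri-axial acceleration (m/s²), angular velocity
(°/s) and magnetic field (µT) — at 30, 60 or 120 Hz. A clinician wants two
numbers per time instant: the elbow flexion–extension angle δ and the
forearm pronation–supination angle Φ, and from them range-of-motion (ROM)
summaries. `elbowkin` implements the full transformation, plus a synthetic
capture generator and an RMSE-based two-system validation workflow.

The pipeline has four computational stages:

1. **Frame transform and static calibration** — express each sensor's
   readings in its segment's anatomical frame and estimate the residual
   sensor-to-segment misalignment from a short static pose.
2. **Attitude fusion** — track each segment's orientation quaternion through
   movement by integrating the gyroscope and correcting toward the
   gravity/field observation.
3. **Joint-angle extraction** — express the forearm orientation in the arm
   frame and project onto the rotation axes assigned to each analytical unit
   of movement.
4. **Validation** — align an estimated series with a reference series and
   report RMSE, bias, and ROM differences.

## Conventions

The anatomical frame is right-handed: **X vertical pointing along gravity
(down), Y anteroposterior (forward), Z mediolateral (right)**. All public
angles are degrees; radians exist only inside function bodies. Quaternions
are Hamilton-convention, scalar first `(w, x, y, z)`, kept in the canonical
sign `w ≥ 0` so that `q` and `−q` denote the same rotation. The default
Euler sequence is intrinsic Z–Y′–X″ (yaw–pitch–roll), matching the
yaw/pitch/roll column labels of optical exports; the sequence is a parameter
everywhere because sensor firmware conventions vary.

The accelerometer at rest reads the *reaction* to gravity: +1 g opposing
the gravity vector, i.e. `(-9.81, 0, 0)` in anatomical coordinates. The
earth magnetic field defaults to 48 µT with 35° dip, horizontal component
along +Y. Both are configuration inputs (`anatomical_gravity()`,
`anatomical_field()`).

## Static calibration

With the subject upright, arms at the sides and palms facing the body
(joint angles defined as 0°), each sensor's stream is first rotated by its
configured mounting rotation `R_i = Rx(δ_odd) Ry′(δ_even)` (intrinsic; the
arm sensor's first angle defaults to 270°, all other deltas to 0°). Over
the `n` static samples the component-wise means of acceleration and field,
`ā_i` and `b̄_i`, are formed, and an orthonormal basis is built:

- `v1 = ā / ‖ā‖` — along the measured gravity reaction,
- `v2 = (v1 × b̄) / ‖v1 × b̄‖` — perpendicular to gravity and field,
- `v3 = v1 × v2`,
- `B_i = [v1 v2 v3]` (column-wise; a proper rotation by construction).

The forearm sensor is the reference frame: placed over the ulna and radius
where soft tissue is thinnest, it is taken as well aligned and gets
`M_2 = I` exactly. The arm sensor's calibration matrix is

```
M_1 = B_2 · B_1ᵀ
```

the orthonormal inverse being the transpose. The product order is fixed by
the defining property of the construction: `M_1 R_1` applied to the raw
static measurements must return the reference gravity and field directions.
(With `B_2` equal to the identity the two possible orders coincide; tests
pin the property, not the notation.) For a perfectly aligned sensor,
`build_basis` returns a constant signed permutation `reference_basis()`
that maps `(v1, v2, v3)` onto the anatomical axes; it depends only on the
sign conventions above, not on the field dip.

Degenerate poses are refused, not repaired: a near-zero mean acceleration
(`‖ā‖ ≤ 1e-6`) or a field (anti)parallel to gravity (`‖v1 × b̄‖ ≤ 1e-6`)
raises an error naming the offending sensor. The threshold is far below any
physically occurring dip-angle configuration.

## Attitude fusion

The filter state is the segment-to-anatomical quaternion plus a gyro-bias
3-vector. Per sample:

- **Prediction.** The quaternion advances by the exact exponential map of
  the bias-corrected body-frame rate increment `ω·dt` (not a first-order
  approximation), then renormalizes.
- **Observation.** `static_orientation(a, b)` builds the gravity/field
  basis from the current accelerometer/magnetometer sample and returns the
  absolute orientation it implies — the same TRIAD-style construction used
  in calibration.
- **Correction.** The error rotation between prediction and observation,
  expressed as a body-frame rotation vector, feeds a proportional attitude
  correction (gain `k_att = 0.5·trust` s⁻¹) and, in the small-error regime,
  an integral bias correction (`k_bias = 10·bias_process·trust` s⁻²).

Three guards decide how much of the observation to trust:

- **Norm gate.** When the accelerometer norm deviates from 1 g by more than
  10 % the weight falls linearly, reaching zero at 20 % — linear
  acceleration along the gravity direction is detectable this way.
- **Rate gate.** `1 / (1 + (‖ω‖ / 20 °/s)⁴)` — the norm gate is blind to
  linear acceleration *perpendicular* to gravity (it barely changes the
  norm), but such acceleration only occurs while the segment moves, which
  the gyro sees directly. The steep exponent makes the gate effectively
  binary.
- **Sustained-static requirement.** Corrections engage only after the
  quasi-static condition has held for 0.3 s. Movement turnarounds show low
  gyro rate for a few samples exactly where tangential acceleration peaks;
  without the dwell requirement those one-signed polluted observations
  ratchet the estimate.

Additionally, a **zero-rate update** estimates the gyro bias directly
(first-order low-pass of the measured rate, time constant 0.5 s) whenever
the stream is detected static — low norm deviation, rate below 3 °/s, no
rate jump from the previous sample — for at least 0.3 s. The bias integral
feedback is restricted to error magnitudes below 1°, so transient
observation errors at motion onset cannot pump the bias state.

These gains are implementer defaults, not values from any reference system;
the contract is behavioral, enforced by the test suite: with zero noise and
bias, fusion equals pure gyro integration equals ground truth; under a
constant 1 °/s bias the fused error stays bounded (< 2° at 60 s) while dead
reckoning drifts ~60°; and the full pipeline recovers a simulated protocol
within 0.5° RMSE noiseless and 2° under the default noise model.

## Joint-angle extraction

The forearm is expressed in the arm frame, `R_rel = R(q_arm)ᵀ R(q_fore)`.
Flexion–extension is the sagittal-plane projection
`δ = atan2(R_rel[2,1], R_rel[1,1])` — the exact inverse of a Z-axis
rotation matrix on axis, and a stable projection off axis. Pronation–
supination depends on the pose in which the movement is executed:

- **Upright** (arm hanging): the axial rotation axis is the anatomical X.
  The series-level extractor first removes the measured flexion and reads
  the residual rotation about the forearm long axis,
  `Φ = atan2(M[3,2], M[2,2])` with `M = Rz(−δ) R_rel`. At δ = 0 this is
  exactly the printed single-axis form `atan2(R[3,2], R[2,2])`; unlike that
  form it remains meaningful during combined motion (the raw X-axis
  projection flips to 180° as soon as flexion passes 90°, which would
  corrupt any protocol with deep flexion).
- **Elbow flexed 90°**: the forearm long axis lies along Y and the
  extraction is `Φ = atan2(R[1,3], R[3,3])`, which reads through the held
  flexion unchanged.

The low-level `pronation_supination_angle()` implements the pure
single-axis forms for both poses; `angle_series()` applies the
series-level variants, accepts a per-sample pose-mode vector (protocols mix
poses), unwraps ±360° jumps with a 180° threshold, flags — never clips —
flexion outside the physiologic band [−10°, 180°], and reports the
per-sample *off-axis residual*: the rotation angle not explained by the two
assigned axes, a diagnostic for soft-tissue artifact and axis
misassignment.

Repetition counting in `rom_summary()` is a Schmitt trigger across the
mid-range: a repetition is an excursion above `mid + h/2` followed by a
return below `mid − h/2`, with `h` 20 % of the range — robust to degree-
level noise by construction.

## The synthetic session generator

`simulate_session()` forward-simulates the capture the hardware would
produce. Its defaults *are* the study conditions: 60 Hz sampling, a 2 s
static calibration-pose head, then the standard three-phase protocol
(`protocol_standard()`): elbow flexion 0→90°×5, flexion 0→145°×5, and
pronation–supination ±80°×5 with the elbow flexed to 90°, five repetitions
per phase at 2.82 s per repetition — a session of ≈ 45.3 s, mirroring the
reference capture duration. The 145° and ±80° maxima are conventional
physiologic values (the protocol only prescribes "maximum possible").

Design choices, made once and documented here:

- **Velocity profile**: raised cosine per repetition (smooth, bounded
  jerk); a trapezoidal profile is available for constant-rate tests.
- **Pose transitions**: when a phase requires a different held elbow angle
  (0° → 90° before the pronation block) a 1 s smooth transition is
  inserted.
- **Angular velocity** is derived from exact finite rotation increments
  `rotvec(Q_kᵀ Q_{k+1}) / dt`, so the gyro channel integrates back to the
  commanded angles to machine precision.
- **Linear acceleration**: the forearm sensor sits at the lower third of a
  25 cm forearm (28 cm arm), offset 3 cm laterally from the bone axis (skin
  surface). Its position's second finite difference adds the tangential and
  centripetal terms to the accelerometer — deliberately exercising the
  fusion gates. The arm is held stationary.
- **Noise model** (defaults): white Gaussian noise of 0.05 m/s² (accel),
  0.2 °/s (gyro), 0.5 µT (mag), plus a constant gyro bias of 0.5 °/s
  magnitude, all in the sensor frame, seeded and bit-reproducible.

What the generator does **not** emulate: soft-tissue artifact (sensors
wobbling on muscle), magnetic disturbance fields, sensor-to-sensor clock
skew, quantization, or wrist/hand interference. Passing the end-to-end
tests therefore demonstrates correctness of the mathematics and robustness
to sensor-grade noise and bias — not performance on a live subject, where
reported inter-system errors of a few degrees are dominated by exactly the
physical factors the desk simulation excludes. The package makes no claim
to reproduce any published human-capture error figure.

## Validation workflow

`align_series()` unwraps both series, resamples them by linear
interpolation onto the grid of the lower-rate series over their common
support, and estimates the inter-system lag by maximizing normalized
cross-correlation over ±2 s (configurable); flat series are flagged
degenerate with lag 0 rather than failing. `rmse()` is the standard
√(Σ(aᵢ−bᵢ)²/N). `compare_systems()` reports RMSE, bias, ROM difference,
lag and sample count per movement channel.

For optical references, `reference_angles()` converts the per-rigid-body
Euler columns to matrices and pushes them through *the same*
relative-rotation and extractor path as the wearable pipeline, so the two
systems are reduced to angles by identical mathematics — any systematic
extractor quirk cancels in the comparison.

## Numerical choices and problem sizes

- Orthonormality/determinant tolerance for rotation matrices: 1e-9;
  quaternion norm restored after every operation.
- Gimbal band: `|sin(middle)| ≥ 1 − 1e-9` → degenerate flag, third angle
  set to 0, first angle carries the combined rotation.
- Text formats write 6 decimal places by default; all readers accept runs
  of spaces/tabs, blank lines and trailing whitespace, decimal point only.
- The kinematic writer buffers 120 lines per flush (the device-side
  convention); content is buffer-size invariant and the flush count is
  returned for observability.
- The test suite exercises: 1000-rotation conversion sweeps; static
  sessions of 60–120 samples for calibration; one 45.3 s / 60 Hz session
  per noise condition for the end-to-end checks (cached across tests); a
  60 s drift scenario; and 10 s alignment fixtures. These sizes keep the
  default run comfortably within an interactive minute-scale budget while
  leaving every property tight.

## Known limitations

- Single-axis joint model: no carrying angle, no shoulder or wrist chain.
- The filter's magnetometer path assumes a clean field; indoor disturbance
  rejection is out of scope.
- In the flexed-90° pose the flexion channel is exact only at 90° held
  flexion; combined large deviations from the held pose bleed into δ by
  design of the single-axis assignment (visible in the off-axis residual).
- Time alignment by cross-correlation assumes the two systems captured the
  same motion; it cannot recover drifting clocks.
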
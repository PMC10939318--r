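---
title: "Methods: stride-level gait analysis from foot-worn IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stride-level gait analysis from foot-worn IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridewise)
```

stridewise reconstructs spatio-temporal gait parameters — stride time,
swing and stance time, stride length, gait velocity — from a single
inertial measurement unit (IMU) worn on each foot. This vignette explains
the models and procedures behind each stage, the parameters that matter,
the synthetic-data generator that provides ground truth for testing, and
the numerical choices and limitations a careful user should know about.

## Data model: units, frames, conventions

All accelerations are in m/s², all angular velocities in deg/s, distances
in m, times in s. Orientations are unit quaternions stored in
`(x, y, z, w)` order under the Hamilton convention, used as *active*
rotations. All interval-like objects (strides, gait events, zero-velocity
regions) use 0-based, half-open `[start, end)` sample indices; serialized
JSON files carry the convention string `"0-based,half-open"`.

Three coordinate frames are distinguished. The *sensor frame* is the
physical IMU frame; for a foot mount we expect x pointing roughly forward,
y to the left and z up when the foot is flat. The *body frame* is the
anatomical frame with axes pa (posterior→anterior), ml (medial→lateral)
and si (superior→inferior). The *world frame* is gravity-aligned and is
where displacement is reported.

The body frames of the left and right foot are mirror images, so identical
anatomical motion produces identical body-frame signals on both sides —
the property that lets one event detector serve both feet. The axis maps
are `pa = +x`, `si = −z` on both sides and `ml = +y` (left) / `ml = −y`
(right). One map is therefore improper (determinant −1). Acceleration
transforms as an ordinary vector; angular velocity is a *pseudovector* and
picks up the determinant as an extra sign (`gyr_body = det(M)·M·gyr`),
which is exactly what makes the mirror-image property hold for rotations
as well. A static, upright sensor reads `acc_si = −9.81` in the body frame
(si points downward); this sign choice is one consistent convention and is
stated here because alternatives exist in the literature.

## Gravity alignment

`align_to_gravity()` detects static regions by sliding a 100 ms window
(1-sample hop) over the gyroscope norm and thresholding the window
maximum at 10 deg/s. The conservative *max* metric matters: windows whose
mean is small can still contain single samples from the end of swing, and
at heel strike the foot can be nearly rotation-free while still
decelerating hard, so a single admitted sample can carry accelerations of
tens of m/s². For the same reason only the *interior* of each static
region (eroded by half a window at both ends) contributes to the pooled
mean acceleration. The recording is then rotated by the single
shortest-arc rotation mapping that pooled mean onto `(0, 0, 9.81)`
(specific-force convention: a static, level sensor reads +g along +z).
Antiparallel vectors are resolved deterministically by a 180° rotation
about x.

## Stride segmentation: subsequence DTW

Strides are found in the continuous body-frame `gyr_ml` signal by matching
a single-stride template with subsequence dynamic time warping. The
accumulated-cost recursion uses steps {diagonal, vertical, horizontal}
with a free start in the signal (the first template row is initialized to
the local cost); the local cost is the squared difference of
amplitude-scaled samples (both template and signal are divided by the
template's `scaling`, 500 deg/s by default). The accumulated cost is *not*
length-normalized, so the `max_cost` acceptance threshold scales with
template length; the shipped default (`max_cost = 5`) is roughly half the
cost of matching the default template against a flat signal, i.e. well
below any spurious-match cost but far above the cost of a genuine stride
under realistic noise.

Match ends are the right edges of the cost valleys of the final DP row.
On idealized signals the valley bottom is an exact plateau (flat stance
matches the template's flat tail at zero cost for any warping), and its
right edge coincides with the onset of the next swing — segmented strides
then run exactly toe-off to toe-off. Under sensor noise the plateau drifts
upward by the accumulated squared noise; a small hysteresis
(`end_tolerance`, default 1e-4 in scaled-cost units) absorbs that drift.
The default is two orders of magnitude above the drift expected from
0.1 deg/s gyroscope noise over one stance, and one order of magnitude
below the cost increment of the first sample of a swing onset, so it
changes nothing on noise-free signals and keeps borders pinned under
noise. Match starts come from the best warping path (ties prefer diagonal,
then vertical, then horizontal steps, which keeps the all-diagonal path on
self-similar signals). Overlapping candidates are resolved by keeping the
lower-cost match (ties: the earlier one), and matches outside the
0.6–3.0 s duration bounds are discarded; both bounds are config-exposed
and non-normative.

The constrained variant forbids runs of more than `max_local_run`
consecutive vertical or horizontal steps, solved exactly by splitting the
DP state per cell into "arrived by diagonal" and "arrived by
vertical/horizontal with run r". `max_local_run = Inf` dispatches to the
plain algorithm, making the two bitwise identical in that limit. Memory
for the constrained DP is O(N·M·max_local_run).

The packaged default template is the `gyr_ml` trace of one noise-free
simulated stride at 204.8 Hz (toe-off to toe-off: swing arc followed by
flat stance), shipped as a versioned JSON fixture and regenerable with
`synthetic_stride_template()`. `snap_to_min()` can refine borders to local
signal minima, but the default pipeline does not use it: with exact
plateau handling the DTW borders are already on the stride boundaries, and
on flat stance a window argmin is close to arbitrary.

## Gait events

Within each segmented stride, `detect_events()` extracts three events from
body-frame signal features. The swing peak is the argmax of `gyr_ml`
(swing produces the dominant positive `gyr_ml` rotation under this
package's sign conventions). Terminal contact (tc, toe-off) is the
negative-to-positive zero-crossing of `gyr_ml` immediately preceding the
swing peak, implemented as the last non-positive sample before the peak;
when the signal is already positive at the first stride sample the
crossing coincides with the stride border itself, and the border is
reported — segmented strides start at toe-off, so this is the boundary
case, not a failure. Initial contact (ic, heel strike) is the argmin of
`acc_pa` within the window from the swing peak to
`ic_search_fraction` (default 0.5) of the stride length after it; the
"filtered" variant first applies a zero-phase (forward–backward)
Butterworth low-pass (order 2, 15 Hz) to `acc_pa`, which matters only
under noise. Mid-stance (`min_vel`) is the center of the 100 ms window
with minimal gyroscope-norm energy after ic. Strides where any rule has an
empty search domain are flagged `detectable = FALSE` rather than dropped.
All window fractions and filter parameters are config-exposed; none are
normative.

`to_min_vel_strides()` re-segments events into strides spanning
`[min_vel_k, min_vel_{k+1})`, whose borders are zero-velocity instants —
the form trajectory reconstruction needs. Non-detectable strides split the
sequence; an unbroken sequence of n strides yields n−1 min_vel strides.

## Zero-velocity detection

Three window-threshold detectors (100 ms windows, 50% overlap by default,
merged into maximal regions): ARED thresholds the mean squared gyroscope
norm; the norm detector thresholds a chosen metric (mean, max, variance)
of a chosen sensor's norm; SHOE combines the accelerometer residual
against a per-window gravity direction estimate with the gyroscope energy,
each scaled by its noise parameter. As σ_a → ∞ SHOE reduces to ARED
scaled by 1/σ_g², a limit the tests verify both ways. Default thresholds
(ARED 25 (deg/s)², norm 34 deg/s, SHOE 50) are calibrated so a still foot
with ~1 deg/s gyroscope noise passes; they are not normative. A final
window aligned with the recording end is always evaluated so every sample
is covered by at least one window.

## Trajectory reconstruction

All methods first convert degrees to radians (exactly once, at module
entry), propagate orientation by first-order quaternion exponential steps
`q_{k+1} = q_k ⊗ Δq(ω_k Δt)`, and integrate velocity and position by the
trapezoidal rule with Δt fixed by the sampling rate.

`madgwick()` augments gyro propagation with β times the normalized
gradient of the accelerometer-gravity objective. The correction is
converted to an equivalent angular rate before the exponential step, so
β = 0 reproduces `integrate_gyro()` bitwise and the normalized gradient
yields constant-rate (≈ 2β rad/s) convergence onto the measured gravity
direction.

Two dedrifted double-integration schemes serve per-stride and per-bout
reconstruction. *Forward–backward* integration assumes zero velocity at
both region borders, integrates velocity forward and backward, and blends
the two with a sigmoid ramp (steepness 10 over the region), cancelling
linear drift; vertical position is linearly detrended
(level-walking assumption). *Piecewise-linear dedrifting* measures the
integrated velocity at each ZUPT-region midpoint, interpolates a drift
series linearly between midpoints (held constant outside), subtracts it,
and clamps velocity to exactly zero inside ZUPT regions; a constant
accelerometer bias produces linear velocity drift, which this model
removes exactly between ZUPTs.

`rts_kalman()` is the reference method: an error-state Kalman filter with
Rauch–Tung–Striebel smoothing. The nominal trajectory is pure strapdown;
a 9-dimensional error state (δp, δv, δθ) with world-side multiplicative
orientation error is propagated with transition blocks `I·Δt` (position ←
velocity) and `−[R·acc]×·Δt` (velocity ← attitude). Every sample inside a
ZUPT region contributes a velocity-is-zero pseudo-measurement
(noise 0.01 m/s by default). The error state is deliberately *not*
injected during the forward pass: injecting and resetting at each update
would zero the stored error trajectory and leave the backward pass nothing
to smooth. Instead the accumulated errors are RTS-smoothed
(`C_k = P_k F_kᵀ P⁻¹_pred,k+1`) and injected once per sample at the end
(`p + δp`, `v + δv`, `Δq(δθ) ⊗ q`). The forward-only (filtered)
trajectory is returned alongside for comparison; smoothing provably never
increases the error covariance, and on noisy simulations it lowers the
mean position RMS — on any *single* session the realized errors can go
either way by a few percent, which is why the tests compare means over
seeds. Process noise defaults (accel 0.05 m/s²·√s, gyro 0.05 deg/s·√s)
and the initial covariance are simulator-calibrated and non-normative; a
tiny position process noise (1e-12·Δt) keeps the predicted covariance
invertible for the smoother gain without affecting estimates. Covariances
are symmetrized each step and updates use the Joseph form.

## Parameters

Temporal: `stride_time_k = (ic_k − ic_{k−1})/rate`,
`swing_time_k = (ic_k − tc_k)/rate`, `stance_time = stride_time − swing_time`.
The first stride of each sequence has only a swing time; missing events
yield NA, never zero. Spatial: stride length is the Euclidean norm of the
*ground-plane* (x, y) displacement between the min_vel-stride borders —
the level-walking convention; the 3-D norm is available behind `use_3d`.
`gait_velocity = stride_length / stride_time` holds as an identity for
every stride.

## Evaluation harness

`match_stride_lists()` matches detected against reference strides: a pair
is feasible iff both border distances are within the tolerance (30 ms by
default, converted to samples by rounding half up — stated because it
affects edge cases). Among feasible pairings a maximum-cardinality
one-to-one matching is computed by successive shortest augmenting paths;
ties between equally large matchings are broken by total border distance,
then by preferring earlier references. A maximum-cardinality (rather than
greedy) matching makes the score independent of list order; an exhaustive
assignment oracle keeps it honest in the tests. Precision, recall and F1
follow the standard formulas with *NA flags* (not zeros) for empty
denominators.

`parameter_errors()` reports per-stride signed/absolute errors and two
aggregation levels: per test (over strides within one recording) and per
fold (over the per-test values within a CV fold). The two schemes weight
recordings differently and generally disagree — the tests construct an
explicit case where the medians differ — so results from different
aggregation schemes must never be compared directly.

`grouped_cross_validation()` assigns whole groups (participants) to folds
by a seeded shuffle dealt round-robin, guaranteeing no group appears in
both train and test; an optional `fit` callback tunes pipeline parameters
on the training items only. Fold assignment is reproducible from the seed
and returned for the run manifest.

## The synthetic gait simulator

`simulate_session()` is the package's ground-truth engine, emulating
straight-line level walking recorded at 204.8 Hz (the reference rate used
throughout; any rate can be configured). Strides follow the
toe-off-to-toe-off convention: swing, then stance. Defaults — 1.3 m
strides of 1.1 s with 60% stance, 5 cm clearance, 35° dorsiflexion arc —
describe unhurried healthy adult gait. Stride time is realized on the
sample grid (`round(stride_time·rate)` samples), and the bundled ground
truth reports the realized values.

Swing kinematics are C² composites: forward displacement follows a
minimum-jerk-style velocity profile (quintic-smoothstep rise and fall);
the vertical clearance arc is `sin⁴(πs)`; sagittal pitch follows a single
smooth dorsiflexion dip `−A·sin²(πs)`. Two deliberate shape choices tie
the kinematics to the event definitions. First, the forward velocity ends
in a short (14 ms) braking pulse emulating the heel-strike impact
transient, completing three-quarters of a sample before touchdown; this
places the `acc_pa` minimum within two samples of the true ic and leaves
the touchdown sample itself consistent with a zero-velocity measurement.
Second, the pitch profile omits the initial plantarflex lobe of real
push-off: `gyr_ml` rises from exactly zero at toe-off, so the
zero-crossing event definition coincides with the kinematic
stance-to-swing boundary. Real signals put a negative `gyr_ml` lobe before
toe-off, which shifts the detected crossing slightly into swing; this
simplification is the price of an exactly known tc.

The IMU synthesis is the exact inverse of the package's strapdown
discretization: world acceleration from central second differences of
position, rotated into the sensor frame with gravity added; gyroscope
readings from per-sample relative quaternions. Trapezoidal integration of
central-difference acceleration telescopes to the central-difference
velocity, so round trips are exact at every stride anchor; the only
residual is a 1–2-sample, ~2 mm transient inside the brake pulse (local
truncation `a·Δt²/4` at ~500 m/s²), with no accumulation. White Gaussian
noise and a constant gyroscope bias are optional and seeded.

Ground truth: tc at the stance→swing transition, ic at swing→stance,
min_vel at the stance midpoint. ZUPT regions are the stance phases plus
the lead-in and inter-bout rests, *excluding the touchdown sample*, whose
central-difference velocity still carries the transient tail — including
it would feed the Kalman filter one knowingly wrong measurement per
stride and measurably degrade the smoother.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: turning, stairs, pathological gait signatures,
stride-to-stride variability within a session, soft-tissue and mounting
artifacts, gyroscope random walk (only white noise and constant bias),
magnetometer effects, and the plantarflex push-off lobe noted above.
Heading is constant and unobservable by ZUPTs; no heading accuracy is
claimed anywhere.

## Problem sizes used in the shipped tests

The test-suite and the acceptance script run entirely on simulated data:
oracle comparisons use signals up to 500 samples and templates up to 50;
recovery tests use sessions of 3–10 strides across seeded random
profiles; the end-to-end benchmarks use one noise-free 40-stride and one
noisy (σ_g = 0.1 deg/s, σ_a = 0.02 m/s²) 50-stride session. These sizes
exercise every code path at full rate (204.8 Hz) while keeping a complete
run comfortably fast on one CPU.

## Known limitations

* The constrained DTW's exact state-space DP is memory-hungry
  (O(N·M·R)); for long recordings use the plain variant or split the
  signal.
* Stride lengths assume level walking; slopes violate both the vertical
  detrending and the ground-plane length convention.
* The maximum-cardinality matcher is exact but not optimized for
  thousands of strides per recording.
* Default thresholds (DTW `max_cost`, ZUPT thresholds, Kalman noise
  densities) are calibrated on the simulator and should be re-tuned on
  real data via `grouped_cross_validation()`.
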
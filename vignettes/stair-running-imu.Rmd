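---
title: "Estimating stair-running foot kinematics from a foot-mounted IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating stair-running foot kinematics from a foot-mounted IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stairgait)
```

## The estimation problem

A shoe-mounted IMU measures body-frame specific force $a_f$ and angular
rate $\omega_f$. Naive double integration of such signals diverges within
seconds because gyro bias tilts the estimated gravity direction and every
tilt error of $\varepsilon$ radians leaks $G\varepsilon \approx 0.17$
m/s$^2$ per tilt-degree into the horizontal acceleration. The structure of
stair running supplies exactly the constraints needed to contain this:

* the foot is essentially stationary for part of every stance phase, which
  (i) exposes the gravity vector to the accelerometer, (ii) pins the true
  velocity to zero, and
* every footfall lands on a tread whose elevation is an integer multiple
  of a known riser height $H$.

`stairgait` exploits all three constraints in sequence. This vignette
records the model, the tunable parameters, the numerical choices, and what
the synthetic test harness does and does not demonstrate.

## Stationary-period detection

A sample is a stance candidate iff
$\lVert\omega_f\rVert < \omega_{thr}$ **and**
$\bigl|\lVert a_f\rVert - G\bigr| < a_{thr}$; the conjunction is essential
because the accelerometer alone cannot rule out constant-velocity motion
and the gyro alone misses pure translation. Candidates are cleaned
morphologically (closing over gaps $\le$ `stance_gap_s`, opening below
`stance_min_s`). Running stance is brief — roughly 45–55% of strides of
0.4–0.9 s — so the defaults ($\omega_{thr} = 0.8$ rad/s, $a_{thr} = 1.0$
m/s$^2$, minimum 4 samples at 128 Hz) are looser and shorter than walking
defaults. These per-sample gates must stay loose to tolerate sensor noise,
which admits a failure mode: just before foot-strike the foot briefly
"floats" with small rates and near-1 g specific force. A second tier
therefore validates each candidate interval on its *mean* statistics: a
genuinely stationary interval has interval means far below the gates
(measured on the simulator: $\le 0.09$ rad/s and $\le 0.24$ m/s$^2$,
versus $\ge 0.2$ rad/s / $\ge 0.36$ m/s$^2$ for pre-strike floats), so
intervals above `stance_mean_factor` (default 0.3) of the gates are
rejected. Each surviving interval contributes one *anchor* at its temporal
midpoint.

## Orientation: quaternion strapdown with a tilt Kalman filter

Between anchors the unit quaternion is propagated by the exact
exponential-map step
$q_{k+1} = q_k \circ \exp([\,\bar\omega_k\,\Delta t\,]/2)$ with midpoint
rates, rather than first-order Euler integration of $\dot q = \tfrac12 q
\circ \Omega$; at 128 Hz with multi-rad/s foot rotations the exponential
map removes the integration-scheme error entirely (a constant-rate
rotation is reproduced to numerical precision over tens of seconds; the
Euler scheme is retained behind `euler_integration` for comparison).

During each stationary interval the interval-mean accelerometer reading
supplies tilt observations
$$\phi_a = \sin^{-1}(a_x/G), \qquad
  \theta_a = -\sin^{-1}\!\bigl(a_y/(G\cos\phi_a)\bigr),$$
with arguments clamped to $[-1, 1]$ and the observation declared invalid
within `eps` of gimbal tilt. The package's Euler convention is defined to
make these formulas exact inverses of the orientation parameterization
(z-up navigation frame; roll about the forward axis, pitch about the
lateral axis, yaw about vertical; composition
$R = R_z(\psi) R_y(-\phi) R_x(-\theta)$), and a round-trip test pins the
convention down.

A linear two-state Kalman filter on (roll, pitch) fuses the gyro-derived
tilt with the observation **once per interval** — stance accelerometer
samples are serially correlated, and per-sample updating would recount the
same information. The update is applied by re-embedding the corrected
roll/pitch into the quaternion with the gyro yaw untouched (yaw is
unobservable without a magnetometer; its pre/post-update equality is
asserted to $10^{-12}$). Covariances: the measurement is
`orient_meas_deg` = 1° of tilt, the initial uncertainty `orient_p0_deg` =
5°. The process noise is a tilt random walk of `orient_process_deg` =
0.4°/√s. This is deliberately an order of magnitude above the pure
angle-random-walk of a consumer gyro: the dominant tilt error between
stance updates is *uncompensated bias drift*, not white noise, and a
filter tuned to the white-noise floor alone trusts the gyro so much that
it lags the bias by several degrees. With the default tuning a 0.5°/s
bias — which drifts an open-loop integration by 30° in a minute — is held
below 1.3° of tilt error, and the tuning depends only on the sensor
class, not on the wearer.

## Trajectory: strapdown integration, ZUPT, riser-ladder elevation

Free acceleration is $a_n = R(q)\,a_f - [0,0,G]$ in the z-up navigation
frame; the sign convention is fixed by the testable contract that a
stationary, correctly oriented sensor yields $a_n \equiv 0$. Velocity and
position follow by trapezoidal cumulative integration from rest.

**ZUPT.** The interval-mean velocity at each anchor is pure drift. The
drift history is modelled as piecewise linear in time through the anchor
residuals (zero at the recording start); after the last anchor it is
extrapolated with the final inter-anchor slope, because the drift source
persists rather than stopping at the last footfall. Subtracting this
function zeroes the anchor velocities exactly; for a constant
accelerometer bias $b$ the correction is exact everywhere between
anchors, and in general the residual is bounded by the curvature of the
true drift over one anchor spacing ($\le b\,\Delta t/2$ for the
triangular worst case). Position is re-integrated from the corrected
velocity. Using interval means (rather than single-sample values) makes
the anchors robust to one-sample boundary misdetection.

**Elevation.** Footfall anchors are snapped to tread indices
$n = \mathrm{round}(p_z/H)$, clipped to advance at most one tread per
footfall in the run direction — the protocol is running without skipping
treads, and the clip tolerates repeated anchors at floor level at the
start and end of a run. A single-state Kalman filter then observes $H n$
at each footfall: process noise `elev_process_m` = 0.03 m per stride (the
per-stride vertical drift scale of consumer MEMS after ZUPT), measurement
noise `elev_meas_m` = 0.01 m (stairs are built to sub-centimetre
tolerances). Each correction is distributed backward over the preceding
inter-anchor segment by linear interpolation in time, keeping the
trajectory continuous, and carried forward in full; only the vertical
component is touched. Whether the backward interpolation should span one
stride or the whole inter-anchor segment is not externally constrained;
the inter-anchor segment is used because it is the span over which the
drift being corrected accumulated. With an injected drift of 0.05 m per
stride the filter holds every footfall within 0.012 m of its tread.

## Gait events from high-frequency wavelet content

Foot-strike and toe-off produce broadband transients; mid-stance and
mid-swing do not. The envelope is the smoothed sum over the accelerometer
and gyroscope *magnitude* channels (orientation-invariant) of squared
detail coefficients of an undecimated (à trous) wavelet transform over
the levels covering `wavelet_floor_hz` = 20 Hz up to Nyquist (levels 1–2
at 128 Hz). Design choices, all config-exposed:

* **Wavelet**: symmlet `sym4`. Shift-invariance of the undecimated
  transform is what makes peak *times* trustworthy; the eight-tap filter
  has four vanishing moments, so below-floor gait content leaks only a few
  percent of its energy into the detail bands (a db2 filter leaks >10%),
  and its near-linear phase keeps transient peaks centred.
* **Thresholding**: a peak counts only above `event_k` = 3 times the
  recording's median envelope — a median-relative rule, so detection is
  invariant to rescaling the input by any positive constant.
* **Search windows**: anchored on the stationary intervals, because
  strike precedes stance and toe-off follows it — waveform-shape rules
  are fragile on stairs where toe-first and heel-first contacts coexist.
  Windows are clamped to the gap between neighbouring intervals (the
  trailing half for strikes, the leading 35% for toe-offs, the fraction
  following from stance kinematics: push-off occupies a fixed early
  fraction of the gap).
* **Strike = onset, toe-off = peak.** The foot-strike is by definition
  the *first* contact transient; the braking deceleration that follows it
  also carries band energy and must not postpone the event, so the strike
  takes the earliest sample reaching `event_rel_frac` = 0.25 of the
  window maximum. The toe-off takes the window argmax.

Stride timing then follows the definitions
$t_{stride} = \Delta t_{strike}$, $t_{stance} = t_{off} - t_{strike}$,
$t_{swing} = t_{stride} - t_{stance}$ (the stance+swing identity is exact
by construction) and $t_{ps} = 100\,t_{stance}/t_{stride}$, with
$t_{ps} > 50\%$ flagging a double-support phase under left–right
symmetry. The first and last footfall of every run are flagged as
transition steps and excluded from steady-state tables, and runs are
separated by stationary intervals longer than `standstill_s` = 1.5 s.

## Stride metrics

With $t_{min}$ the elevation minimizer inside stance (earliest sample on
ties) and $t_{max}$ the last swing local maximum before the strike
(ascent) or the first stance local maximum (descent, with a fallback to
the full stride window):

* clearance $c = p_z(t_{max}) - p_z(t_{min})$;
* kinetic-energy proxy $ke_m = \overline{\lVert v \rVert}^{\,2}/2$ — the
  stride-mean speed is taken first and then squared. The mean-of-squares
  reading is strictly larger whenever speed varies (a 0→2→0 m/s sawtooth
  gives 0.5 vs 0.667) and is available behind `ke_mode` for sensitivity
  analyses, but the squared-mean is the definition;
* bounce angles $\theta_{break} = |\theta(t_{strike}) - \theta(t_{min})|$,
  $\theta_{prop} = |\theta(t_{off}) - \theta(t_{min})|$,
  $\theta_{bounce} = \theta_{break} + \theta_{prop}$, on pitch unwrapped
  over the stance window;
* GRF proxy $gf_m = (v_z(t_{off}) - v_z(t_{strike}))/t_{stance}$, the net
  vertical impulse rate. No gravity term is added: as defined, a
  momentum-preserving stance scores zero, which is precisely what
  distinguishes descent (gravity does the work) from ascent (the leg
  generates net upward impulse). Adding $g$ would measure the physical
  ground reaction instead; the as-defined quantity is kept because its
  zero-for-descent signature is the interpretable one.

Event-time lookups use nearest-sample values — events are sample-quantized
by detection anyway.

## The synthetic test harness

`simulate_foot_trajectory()` builds a single-foot piecewise-polynomial
path over a staircase (default riser 0.18 m, tread 0.30 m, 128 Hz): a 2 s
standstill, then per stride a smooth swing to the next tread and a stance
split 40/20/40 into braking (landing dip, pitch sweep-in), a quiet
plateau (the truly stationary window), and push-off (pitch sweep-out).
Quintic Hermite segments make velocity the exact analytic derivative of
position. Ascent swings carry an apex solved so the commanded clearance
(default 0.05 m) is exact over the stance minimum; descent swings are
near-linear, with the commanded clearance (default 0.02 m) realized by
the landing dip as the foot rolls over the tread nose. The stance pitch
sweep (default 45°) is monotone, so the bounce angle equals the commanded
sweep regardless of where $t_{min}$ falls. Landing and take-off vertical
velocities default to −0.4 / +0.5 m/s (ascent) and −0.4 / −0.4 m/s
(descent), making the ascent GRF proxy ≈ 3.3 N/kg and the descent proxy
zero — the qualitative contrast of interest. One simulated footfall rises
one riser, mirroring the alternating left/right tread sequence of the
real task for the ladder bookkeeping.

`synthesize_imu()` inverts the navigation equation
($a_f = R^\top(a_{nav} + [0,0,G])$, $\omega_f$ the true body rates) and
adds consumer-MEMS-grade errors: per-axis biases (0.3°/s, 0.03 m/s$^2$),
seeded white noise (0.1°/s/√Hz, 0.01 m/s$^2$/√Hz), and ±15 ms
exponentially decaying 40 Hz bursts at the true event times so the
wavelet detector sees transients with known timing. The burst carrier is
odd around the event so the sampled burst carries no net impulse, and the
ring is carried mostly by the lateral accelerometer and roll/yaw gyro
axes: the magnitude-channel detector sees its full energy while the
vertical velocity and pitch — the metric-bearing integrals — see only the
mm/s-scale residues a real, much higher-frequency shoe vibration would
leave. (At 128 Hz the carrier cannot exceed 64 Hz; a 40 Hz vertical burst
of realistic amplitude would imply a ~0.2 m/s vertical velocity
excursion, an artifact of the forced-low carrier, not of real impacts.)
An optional `clip_g` reproduces range saturation. All randomness is
seeded and the caller's RNG state is restored.

Ground-truth per-stride metrics are computed from the truth kinematics
*with the same metric definitions* used on estimated data; the simulator
never calls estimation code, so recovery tests are not self-fulfilling.

**What passing these tests shows** — that the estimation chain inverts
the measurement model it assumes, with correct bookkeeping, under
realistic bias/noise magnitudes, across stride periods 0.4–0.9 s in both
directions. **What they do not show** — robustness to what the simulator
omits: soft-tissue and mounting compliance, scale-factor and
g-sensitivity errors, temperature drift, saturation-clipped strikes (the
clip exists but is off by default), non-steady pacing, missed treads, and
staircases whose geometry differs from the assumed ladder. Results on
real recordings depend on those factors and on sensible threshold
configuration for the instrument at hand.

## Statistical reporting

`regress_vs_stride_time()` fits ordinary least squares with stride time
as the response, reporting $R^2$, slope, and the slope's t-test p-value;
`compare_conditions()` runs pooled-variance two-sample t-tests
(stance percentage, clearance, bounce angle), one-sample t-tests of the
GRF proxy against zero per condition, and per-condition F-tests of
swing-versus-stance variance. Strides are pooled across feet (left–right
symmetry) and runs; no per-subject random effects are fitted, matching
the pooled-scatter convention of the underlying field. Residuals are
attached to each regression so external tools can run distributional
diagnostics; the package deliberately does not re-implement them.
Degenerate inputs (zero-variance cells) are flagged rather than tested.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on
simulated runs of 8–10 footfalls (10–12 s at 128 Hz, ≈1300–1500 samples)
and sweep 24 seeded runs across stride periods 0.4–0.9 s in both
directions; these sizes exercise every code path while keeping a complete
run of the suite within seconds on one core. Every stochastic draw is
seeded; identical inputs and configuration reproduce identical outputs
bit for bit.
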
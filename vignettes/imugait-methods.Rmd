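---
title: "Inertial gait analysis with imugait: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inertial gait analysis with imugait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugait)
```

## The problem

A foot- or shank-mounted MEMS inertial unit measures body-frame specific
force $\tilde{a}$ and angular rate $\omega$. Double-integrating those
signals reconstructs the 3-D foot trajectory and from it the
spatio-temporal parameters clinicians use to assess gait: cadence, stride
length, walking speed, maximum foot elevation, ankle range of motion,
stance ratio, and bilateral symmetry. Uncorrected integration drifts within
seconds because of sensor bias; the central trick of the method is that a
walking foot is periodically stationary, so the known zero velocity during
stance can cancel the accumulated error cycle by cycle.

## The strapdown model

The per-sensor state is $(q, v, p)$ — attitude quaternion (Hamilton,
scalar-first, body$\to$navigation), velocity and position in a z-up
navigation frame with gravity $g_n = (0,0,9.81)$ m/s$^2$:

$$\dot q = \tfrac12\, q \otimes (0,\omega), \qquad
  \dot v = q \otimes (0,a) \otimes q^{*} - g_n, \qquad
  \dot p = v.$$

`rk4_attitude_step()` advances $q$ by classical fourth-order Runge–Kutta,
with the midpoint rate taken as the mean of the two adjacent gyro samples
and renormalization after every step (norm drift $<10^{-12}$ over $10^5$
steps). Velocity and position use the trapezoidal rule: the state
equations are continuous ODEs and nothing in the problem justifies a
higher-order scheme for signals already limited by sensor noise. The
round-trip property (simulator $\to$ ideal signals $\to$ forward
integration) reproduces truth positions to $10^{-4}$ m at a 1 kHz test
rate; at the default 100 Hz the residual discretization error behaves like
a slowly varying pseudo-bias, which the zero-velocity stage removes along
with the real one.

**Initial attitude.** Stroke patients cannot be asked to perform alignment
movements, so the initial attitude comes from accelerometer levelling
during the initial standstill: roll and pitch from the mean specific force
(which then reads $-g$ in the body frame), yaw set to zero. Yaw is
unobservable without a magnetometer, and no magnetometer fusion is
performed; the per-trial *forward* direction is instead defined as the unit
horizontal net-displacement direction, which is also the axis used by the
stride-length and speed definitions.

**Standstill calibration.** `calibrate_trace()` uses the first 1.5 s
(wearers stand still before walking) to estimate the static gyro bias and
the local gravity reading $g_\mathrm{ref}$. This matters: the gyroscope's
1°/s bias stability alone would otherwise keep the stance detector's
normalized statistic near its threshold, and an integrated ankle angle
would drift by tens of degrees per minute. During the drift-correction pass
the gyro bias is re-estimated from the mid-stance portions (25–70%) of
every stance run — a zero-angular-rate update. Without it the residual
vertical-axis bias (a heading random walk) bends the reconstructed path and
lateral error grows quadratically with distance walked.

## Stance detection

The per-sample statistic combines both stationarity cues,

$$s_i = \frac{\bigl|\,\lVert a_i\rVert - g_\mathrm{ref}\bigr|}{\sigma_a}
      + \frac{\lVert \omega_i - \hat b_g\rVert}{\sigma_\omega},$$

normalized by the sensor bias stabilities ($\sigma_a = 0.02$ m/s$^2$,
$\sigma_\omega = 1$°/s). A sample is a stance candidate when the centred
mean over a window of $W_d$ samples falls below the threshold $T_d$
(defaults $W_d = 15$ at 100 Hz, $T_d = 3$, both exposed because detection
quality is sensitive to both). A centred mean erodes the edges of quiet
intervals by up to half a window, which would bias the estimated stance
ratio several points low, so each detected run is then extended outward
while the raw per-sample statistic stays below $T_d$ — two-stage
(hysteresis) detection.

**Adaptive duration filtering.** Measurement fluctuations produce short
spurious stance candidates. Candidate durations are clustered into two
groups; in one dimension the minimum within-cluster-sum-of-squares
2-partition is a split of the sorted values, so `kmeans_duration_filter()`
enumerates the splits and returns the exact optimum deterministically (this
is what converged 2-means computes, without seeding artefacts). The cluster
with the larger mean duration is the true one and its extremes become the
adaptive time-constraint bounds. Two guards make this safe on real
segmentations: if the two cluster means are not separated by at least a
factor two the candidates are treated as homogeneous and nothing is
rejected (2-means would otherwise bisect perfectly good strides); and the
first and last candidates are censored — they merge with the lead-in and
lead-out standstill or are truncated by the record, so their durations are
not comparable — and bypass the filter. Stance runs separated by gaps
shorter than 0.1 s are merged first; no human swing is that short. A step
count is the number of accepted stance-to-swing transitions.

**Sub-phases.** Within a stance, the sagittal (mediolateral-axis) angular
rate shows a heel-strike peak and a toe-off peak. Loading runs from stance
start to the first zero-crossing after the heel-strike peak, pushing from
the last zero-crossing before the toe-off peak to stance end, foot-flat is
the remainder; the three tile the stance exactly. If the gyro is
near-constant (no usable peaks or crossings) the stance is returned
unpartitioned with a warning rather than guessing.

## Zero-velocity drift correction

Modelling the accelerometer error as a constant $\varepsilon$ over one
gait cycle, $a_t = \tilde a_t + \varepsilon$, integration from a swing
start (where velocity is re-zeroed) gives
$v_t = \tilde v_t + \varepsilon t$; since the true velocity at swing end is
zero, $\varepsilon = v_{T_{sw}}/T_{sw}$, and subtracting
$\varepsilon\,(t - t_0)$ inside the swing makes the corrected velocity
exactly zero at every swing end. Velocity is pinned to zero throughout
detected stance; position is the trapezoidal integral of the corrected
velocity, hence constant during stance. $\varepsilon$ is estimated in the
navigation frame, consistent with the integral it corrects; the body-frame
bias projection wobbles a few percent as the foot pitches, which the
per-cycle estimate absorbs.

Because the method targets level-ground walking, the vertical displacement
of each swing is additionally de-drifted to zero (`flat_ground = TRUE`).
This flat-ground height update stops the residual levelling-tilt error
(≈0.1° for a 1σ accelerometer bias) from accumulating a couple of
millimetres of height per stride. Smoother-based post-processing is
deliberately not offered: it adds latency and its benefit for this use is
questionable.

## Gait metrics

With touchdown positions $p^{fwd}_i$ (mean stance position projected on
the forward axis) and accepted-stride stance/swing durations:
stride length $S_l = \frac1n\sum_i (p^{fwd}_i - p^{fwd}_{i-1})$
(telescopes to $(p_n - p_0)/n$); gait speed
$G_s = (p^{fwd}_n - p^{fwd}_0)/T$; max foot elevation $E_m$ = per-stride
maximum of the upward position above the stance baseline, averaged;
stance ratio $R_s = t_{stance}/(t_{stance} + t_{swing})$; cadence
$= 60\cdot\text{steps}/T$ where each stride counts as two steps — the
convention that puts a healthy ~1.07 s stride at the familiar
~112 steps/min scale (configurable via `steps_per_stride`). Per-stride
values are aggregated by mean, with dispersion reported as the sample
standard deviation across strides.

The ankle angle is the integral of the sagittal angular-rate difference
between shank and instep sensors plus the difference of their initial
inclinations; the range of motion is its max-minus-min over the trial, in
degrees, and is invariant to the initial-angle constant. Both gyros are
de-biased from their own standstills first — without that, 1°/s of
differential bias would add ≈19° of spurious drift over a 30-stride trial.

**Symmetry.** $GS = 1 - 2\,|X_a - X_s|/(X_a + X_s)$ compares a parameter
between affected and sound limbs: 1 at perfect symmetry, decreasing as the
sides diverge, scale-invariant. The absolute difference is used so that
$GS \le 1$ and "higher is more symmetric" holds regardless of which side
is labelled affected; the raw signed variant (which exceeds 1 when
$X_a < X_s$) is available behind `signed = TRUE`.

**Reference ranges.** Reports flag each metric against healthy-adult
normal ranges shipped as configuration data
(`inst/extdata/reference_ranges.json`), derived from published group
statistics as mean ± 2 s — the conventional clinical normal-range width;
mean ± 1 s would flag a substantial share of unremarkable healthy trials,
including the package's own healthy preset, whose internally consistent
walking speed (stride length × cadence/2 ÷ 60 ≈ 1.11 m/s) sits more than
1 s below the group mean speed. These ranges are a visual reference for
reading a report, not medical criteria.

## Mounting-position estimation

With the IMU at fixed ratio $k$ along the segment between joints 1 and 2,
$p(t) = p_1(t) + k\,(p_2(t) - p_1(t))$. The Kalman state is $(v, s, k)$
with $\dot v = a$, $\dot s = v$, $\dot k = 0$; the observation equates the
measured joint-1 displacement with
$k\,[(p_1(t)-p_1(0)) - (p_2(t)-p_2(0))] + s(t)$. Treating the measured
joint displacements as known regressors makes the observation linear in
the state, so no relinearization is needed. Numerical choices: the
deterministic propagation uses a two-step Adams–Moulton velocity increment
and a second-order position update (a first-order scheme leaves a
velocity offset that the filter misattributes to $k$ at exactly the
10$^{-3}$ level the recovery is specified to); the covariance update is in
Joseph form, keeping it symmetric positive semi-definite; the prior is
$k = 0.5 \pm 0.5$ (uninformative mid-segment) with 1 mm default joint
measurement noise. Under pure translation the joint displacements
coincide, the $k$ column of the observation vanishes, and the filter
reports `unobservable = TRUE` with an unshrunk $k$ variance instead of
failing — rotational motion is what makes the mounting position
identifiable.

## The synthetic-trial simulator

The simulator provides what an optical reference system provides in a
laboratory validation: ground-truth trajectories, events and metric values
against which the pipeline is scored, except that here the truth is exact.
A `gait_template()` fixes the commanded kinematics; the healthy preset uses
stride length 1.19 m, stance fraction 0.62, foot clearance 0.24 m, ankle
ROM 70° and stride time 60/56 s (cadence 112 steps/min). These group means
are not mutually consistent as one kinematic template — stride length ×
cadence implies 1.11 m/s, not the separately tabulated 1.34 m/s — so the
preset keeps the spatial and temporal values and lets speed follow from
them. The stroke preset uses hemiplegic group means (stride 0.87 m,
cadence 85, stance 73%, clearance 0.13 m, ROM 52°) with affected-side
asymmetry factors on stance time (0.85), clearance (0.6) and ROM (0.75):
hemiplegic gait shortens the affected limb's stance and flattens its
swing, while stride length and stride time are necessarily shared between
feet in steady walking.

Each stride is a stance (foot fixed, tiny 0.1° heel-strike and toe-off
pitch rotations so the sub-phase gyro signature exists without breaking
the zero-velocity assumption) followed by a swing: minimum-jerk (quintic)
forward advance and a C² vertical clearance arc. The arc's vertical
acceleration is an envelope-hugging tilted plateau right after toe-off, a
broad lobe through the apex, and the mirrored braking pulse — the one
shape family we found that lifts 0.24 m in a 0.41 s swing while keeping
the combined specific force of the healthy preset inside the
accelerometer's ±50 m/s² range (peak ≈ 49 m/s²); a naive symmetric bump
exceeds the range. The ankle-angle profile spans the template ROM once per
stride and is quiescent during the standstill. Trials start and end with
2 s of standstill, as instructed wearers do, which is also what the
calibration stage relies on.

Ideal sensor streams come from inverting the state equations:
$a_{body} = q^{*} \otimes (\dot v + g_n) \otimes q$ and, for these
pitch-only profiles, $\omega = (0, \dot\theta, 0)$ exactly. Noise follows
the sensor datasheet where it specifies values — per-trial constant bias
drawn with the bias-stability sigmas (0.02 m/s², 1°/s, 0.1 µT) and
shaping by a 4th-order Butterworth low-pass at the 30/40/10 Hz
bandwidths — and uses consumer-MEMS white-noise floors chosen once where
it does not (per-sample pre-filter sigmas 0.01 m/s², 0.1°/s, 0.5 µT).
Bias is constant per trial; random-walk bias is out of scope. The
magnetometer channel is synthesized (constant field rotated into the body
frame) for I/O completeness only.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: soft-tissue and footwear artefacts, foot
rotation over the toe during push-off (real feet are not rigidly
stationary through all of stance), slopes and turns, bias random walk,
magnetic disturbances, and inter-subject variability beyond the template
parameters. Recovery results on the simulator bound the algorithmic error
of the pipeline, not the full error of a physical deployment.

## Problem sizes and determinism

The shipped checks use desk-scale versions of the study conditions: a
20-stride noisy trial for position-accuracy (per-axis RMSE vs truth,
compared after registering the horizontal frame, since heading is
unobservable to a single foot IMU and any comparison against an external
reference involves such a registration), 50 strides for the gait-cycle
partition, 30 strides of a shank+instep pair for ankle ROM, 56 strides for
step counting, and 4 s swings for mounting-ratio recovery. All randomness
flows through explicit integer seeds; repeated runs are bitwise identical.

## Known limitations

* Heading (yaw) is defined only up to the per-trial forward convention.
* The stance detector's normalizers assume datasheet-level bias
  stability; grossly miscalibrated sensors need `Wd`/`Td` retuning.
* Ankle ROM requires a synchronized shank sensor; unilateral analyses
  report the remaining six parameters only.
* The sub-phase boundary rule (zero-crossings around the two
  stance-adjacent gyro peaks) is one defensible reading of the gait-phase
  literature and is isolated behind `partition_subphases()`.
* Double-stance timing is not estimated from a single foot sensor;
  bilateral metrics require both feet instrumented.
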
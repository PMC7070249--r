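# imugait

Wearable inertial-sensor gait analysis in R: strapdown integration with
zero-velocity updates, adaptive gait-phase segmentation, clinical
spatio-temporal metrics with a bilateral symmetry index, Kalman estimation
of the sensor mounting position, and a synthetic walking-trial simulator
with exact ground truth.

## Who this is for

Clinical-gait and wearable-sensing researchers who record walking with
foot- or shank-mounted MEMS IMUs (tri-axial accelerometer + gyroscope,
optionally magnetometer) and want the standard ambulatory gait report —
without optical motion capture, and without asking patients to perform
alignment movements.

## The method

For each sensor node the strapdown state `(q, v, p)` obeys

    q̇ = ½ q ⊗ (0, ω)        (attitude, integrated by RK4)
    v̇ = q ⊗ a ⊗ q* − gₙ     (gravity-compensated velocity)
    ṗ = v

Raw integration drifts with sensor bias, so the pipeline exploits the
periodicity of walking: stance phases are detected by a windowed
statistic `|‖a‖−g|/σₐ + ‖ω‖/σ_ω < T_d`, candidate phases are validated by
an exact 1-D 2-means duration filter (adaptive time constraints), and
within each gait cycle the constant acceleration error ε is recovered
from the end-of-swing velocity, `ε = v(T_sw)/T_sw`, and removed — the
corrected foot velocity is exactly zero at every stance. From the
corrected trajectory and segmentation the package reports cadence, stride
length `Sl = Σ(pᵢ−pᵢ₋₁)/n`, gait speed, max foot elevation, ankle ROM
`∫(ω_shank − ω_instep)dt` (max−min, degrees), stance ratio
`t_st/(t_st+t_sw)`, and the bilateral symmetry index
`GS = 1 − 2|Xa−Xs|/(Xa+Xs)`. A seven-state Kalman filter estimates where
along a limb segment the IMU is mounted
(`p = p₁ + k (p₂ − p₁)`), flagging the pure-translation case where `k`
is unobservable.

## Worked example

Simulate a 20-stride bilateral healthy walking trial (with a shank sensor
on the left limb), run the full analysis, and print the report:

```r
library(imugait)

trial <- simulate_trial(gait_template("healthy"), n_strides = 20,
                        seed = 42, bilateral = TRUE, shank = TRUE)
g <- analyze_gait(trial$traces$left, trial$traces$right,
                  left_shank = trial$traces$left_shank)
g$limbs$left
#> <gait_analysis> 18 strides over 19.3 s (21.42 m)
#>   cadence 112.0 steps/min | stride 1.190 m | speed 1.111 m/s
#>   stance ratio 0.621 | max foot elevation 0.239 m
g$report
#> <gait_report>
#>   ankle_rom_deg             70.15 deg    [52, 92] ok
#>   stride_length_m            1.19 m      [0.93, 1.45] ok
#>   cadence_spm                 112 steps/min [90, 134] ok
#>   walking_speed_mps         1.111 m/s    [0.99, 1.69] ok
#>   stance_ratio             0.6209        [0.45, 0.73] ok
#>   max_foot_elevation_m     0.2392 m      [0.12, 0.36] ok
#>   gait_symmetry_stance     0.9988        [0.81, 1] ok
```

Eighteen of the 20 strides are reported: the first and last touch the
lead-in/lead-out standstill and are censored. Every metric recovers its
commanded template value (stride 1.19 m, stance 62%, clearance 0.24 m,
ROM 70°) and sits inside the healthy reference band; the near-1 symmetry
index reflects the symmetric simulation. The bracketed ranges are visual
references (healthy group mean ± 2 s), not medical criteria.

Estimating the mounting position of an IMU on a swinging limb segment
(true ratio 0.3 from the proximal joint, 1 mm joint-measurement noise):

```r
sc <- generate_placement_scenario(k_true = 0.3, "rotation", seed = 1,
                                  joint_noise_m = 1e-3)
kalman_install_ratio(sc$trace, sc$joints, q = sc$quat)
#> <placement_estimate> k = 0.3017 (sd 0.0016)
```

A command-line front end is installed at
`system.file("cli/gait.R", package = "imugait")` with `analyze`,
`simulate`, `calibrate-placement` and `report` subcommands (exit code 0
on success, 2 on validation errors).

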
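# freezekin

Spatiotemporal gait analysis from foot-mounted inertial measurement
units (IMUs), for movement-science and clinical-gait researchers who
study Parkinson's disease and freezing of gait (FoG) with wearable
sensors instead of a motion-capture laboratory.

A single instep-mounted IMU (tri-axial accelerometer in m/s², tri-axial
gyroscope in °/s, orientation quaternion, sampled at 100 Hz) carries
enough information to reconstruct, stride by stride:

- **Gait events** from the filtered sagittal angular velocity ω(t):
  heel strike (HS) and toe off (TO) are the two stance-adjacent maxima
  of each stride cycle; toe strike (TS) and heel off (HO) are the
  instants where |ω| crosses a 30 °/s threshold, bracketing the
  flat-foot interval.
- **Four gait phases** as percentages of stride time
  `t(GP)/ST · 100`: loading response (HS→TS), midstance (TS→HO),
  pre-swing (HO→TO), swing (TO→next HS). They sum to 100 by
  construction.
- **Stride time** (consecutive HS interval), **cadence**
  (`⌊strides / minutes⌋`) and the **Gait Phase Quality Index**,
  GPQI = Σ_feet Σ_phases (GP_subject − GP_reference)², a scalar
  distance from a healthy reference phase distribution (lower = better
  gait quality).
- **Stride length and speed** by zero-velocity-update (ZUPT) dead
  reckoning: the specific force is rotated to the global frame with the
  quaternions, gravity is removed, velocity `v(t) = ∫ a(t) dt` is
  pinned to zero on every flat-foot interval with a per-span linear
  detrend, and the horizontal displacement
  `d_H(t) = ∫ √(v_x² + v_y²) dt` yields SL as its maximum between
  successive heel strikes; SP = SL/ST.
- **Foot clearance**: the vertical displacement relative to the
  flat-foot baseline; per swing, landmarks Max1 (first local maximum),
  Min, and Max2 (last local maximum), in mm.
- **Method agreement** against an optoelectronic reference trajectory:
  absolute error |x_OS − x_IMU|, relative error
  |x_OS − x_IMU|/|x_OS|·100, and Bland–Altman bias ± 1.96 SD limits of
  agreement.
- **Group statistics**: Shapiro–Wilk normality gating into two-sided
  Mann–Whitney U (non-normal) or independent-samples t tests (normal)
  over the eight study comparisons (HC vs PDoff/PDon/NOFOGoff/NOFOGon/
  FOGoff/FOGon, NOFOGoff vs FOGoff, NOFOGon vs FOGon).

Because clinical recordings of this kind are not redistributable, the
package ships a first-class **synthetic gait generator**
(`generate_trajectory()`, `simulate_imu()`, `simulate_markers()`,
`generate_cohort()`) that produces ground-truthed, twice-differentiable
foot trajectories and sensor streams; every stage of the pipeline is
validated against that ground truth. See the methods vignette
(`vignettes/freezekin-methods.Rmd`) for the model, its assumptions and
its limitations.

## Worked example

```r
library(freezekin)

p      <- gait_model_params(n_strides = 10, seed = 1)   # healthy defaults
truth  <- generate_trajectory(p)
rec    <- simulate_imu(truth)                  # 100 Hz IMU streams + noise
res    <- extract_gait_metrics(rec)            # full pipeline
print(res)
#> <gait_analysis> 10 stride(s), cadence 57 strides/min
#>   ST 1.050 +/- 0.000 s | SL 1.302 +/- 0.002 m | SP 1.240 m/s
#>   phases LR/MS/PS/SW: 8.6 / 35.2 / 11.4 / 44.8 %
#>   clearance Max1/Min/Max2: 150 / 88 / 118 mm
```

The generator's stated world had ST 1.05 s, SL 1.30 m and a clearance
profile of 150/90/120 mm: stride time is exact, stride length is
recovered to 0.2%, and the clearance landmarks to within ~2 mm (the
small residuals are the documented integration systematics). Validating
the clearance chain against a synchronized synthetic marker track:

```r
markers <- simulate_markers(truth, marker_noise_mm = 1, seed = 2)
val     <- validate_clearance(rec, markers)
print(val$report, digits = 3)
#>   landmark  n eabs_mean eabs_sd erel_mean erel_sd  bias loa_low loa_high
#> 1     Max1 10      2.42   0.387      1.59   0.251 -2.42   -3.18    -1.66
#> 3      Min 10      2.99   0.397      3.29   0.428 -2.99   -3.77    -2.21
#> 2     Max2 10      4.09   0.458      3.34   0.368 -4.09   -4.99    -3.19
```

A negative bias means the IMU chain underestimates the optical
reference, with relative errors in the single-percent range. Cohort
statistics run on the synthetic study population:

```r
cohort <- generate_cohort(cohort_spec())
grid   <- run_comparison_grid(cohort_long(cohort$subjects))
subset(grid, parameter == "SL")   # eight comparisons, stars at 0.05/0.01/0.001
```

A command-line interface mirrors the programmatic API:

```sh
exec/freezekin simulate --out sim/ --n-strides 10 --seed 1
exec/freezekin extract  sim/imu.csv --out metrics.csv
exec/freezekin validate sim/imu.csv sim/markers.csv --out report/
```

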
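---
title: "Methods: foot-mounted IMU gait analysis and its synthetic test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foot-mounted IMU gait analysis and its synthetic test world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freezekin)
```

## The measurement model

A foot-mounted IMU on the instep measures, at 100 Hz, the specific
force $\mathbf{f}(t)$ in the sensor frame (m/s²), the angular velocity
$\boldsymbol{\omega}(t)$ (°/s), and an orientation quaternion
$q(t)$ (scalar-first, Hamilton convention, sensor→global, the
convention published by the major wearable-IMU vendors). During
walking, the sagittal channel of the gyroscope — the sensor $y$ axis,
aligned with the body's mediolateral axis — shows a stereotyped
per-stride morphology: two stance-adjacent extrema at heel strike (HS)
and toe off (TO) bracketing a quiet flat-foot interval, and one
dominant mid-swing extremum of the opposite sign. All event logic in
this package runs on that single channel after zero-phase low-pass
filtering.

### Preconditioning

Order-2 Butterworth low-pass filters, 3 Hz for the gyroscope and 10 Hz
for the accelerometer, applied forward–backward. Zero-phase filtering
is chosen because event *timing* is the quantity of interest and a
causal filter would lag every event by a signal-dependent amount; the
price is that the effective magnitude response is squared (an order-2
design acts as order 4). The implementation designs the filter by the
analog-prototype/bilinear-transform route with frequency pre-warping
(coefficients agree with the reference scientific-Python
implementation to machine precision) and controls edge transients with
odd-reflection padding sized to let the transient decay below 1e-4.

### Event detection

The channel sign depends on which foot the sensor is on and how it is
mounted, so the signal is auto-oriented such that the stance-adjacent
extrema are maxima — equivalently, the dominant mid-swing extremum is
negative. The orientation vote compares the median height of prominent
positive and negative peaks; a height floor equal to the prominence
floor (default 50 °/s) excludes the spurious low "peaks" that the
flat-foot plateau forms between the two stance humps.

Stride windows run between consecutive dominant swing peaks (minimum
peak distance `min_stride_s`, default 0.4 s; windows outside
[0.4, 2.5] s are discarded). Within each window the two most prominent
local maxima are the stance-adjacent events. Between two swing peaks,
heel strike always precedes toe off, so the earlier maximum is HS and
the later is TO; in amplitude the TO (push-off) peak is ordinarily the
larger of the two, which is how we read the classical description of
TO and HS as the "first and second maximum" of a stride cycle. Toe
strike is the first sample after HS at which $|\omega|$ is at or below
the 30 °/s threshold, heel off the first sample before TO at which it
is back at or above it; a sample exactly at the threshold counts as the
crossing. Strides violating `hs < ts < ho < to < hs_next`, or lacking
a flat-foot interval, are dropped and logged — never interpolated.

Walking-bout boundaries ("going" and "returning" on a straight
corridor) are an explicit input; `select_central_strides()` keeps the
10 strides nearest each bout's midpoint (20 per out-and-back trial),
which removes gait initiation, termination and turning.

### Temporal parameters

Stride time is the HS-to-HS interval. Phase percentages are exact
ratios of event intervals to stride duration and sum to 100 by
construction. Cadence is $\lfloor n_\text{strides} /
\text{duration}_\text{min}\rfloor$; the duration is the span from the
first to the last analyzed heel strike, not the raw trial length,
because central-stride selection has already removed the
acceleration/deceleration tails that would otherwise dilute the count.

GPQI compares a subject's phase quadruple on both feet with a healthy
reference (the renormalized componentwise mean of control profiles).
The printed formula in the originating literature is typographically
ambiguous about the radical, so both readings are implemented behind
`gpqi_variant`: `as_printed` (default) is the plain sum over feet of
summed squared deviations; `per_foot_sqrt` is the sum over feet of the
per-foot Euclidean distance. Both are zero iff both feet match the
reference and strictly increase in any single |deviation|. GPQI is
computed on mean phase profiles per subject; computing per stride and
averaging is a documented alternative the data do not distinguish.

### ZUPT dead reckoning

Quaternion rotation takes the specific force to the global frame;
subtracting a constant gravity vector (9.80665 m/s², the standard
value; the choice matters at the fourth decimal of stride length)
leaves the foot's linear acceleration. Integration uses cumulative
trapezoids. Velocity is pinned to zero on every flat-foot interval
(toe strike → heel off); between consecutive flat-foot intervals, a
per-span linear detrend drives the terminal velocity at the next
flat-foot onset to zero on each axis. Per-span anchoring (rather than
one trial-wide detrend) is what makes the integration bounds
consistent with the zeroed intervals; the alternative single-detrend
reading is noted but not used. Horizontal speed
$v_H = \sqrt{v_x^2+v_y^2}$ is re-zeroed on flat foot and integrated
per span; stride length is the maximum of the resulting displacement
between successive heel strikes. Strides without flat-foot anchors on
both sides (the first and last of a bout) are dropped with `NA`.
Clearance repeats the procedure on the vertical axis only, reporting
displacement relative to the flat-foot baseline (the absolute foot
height is unobservable), with Max1/Min/Max2 sought inside the swing
interval; a 5 mm prominence floor on the landmark search rejects
noise-raised spurious maxima.

### Agreement stage

The optoelectronic reference is normalized by subtracting the absolute
minimum of the vertical marker trajectory. An important numerical
caveat, measured on the synthetic world: applied to an *unsmoothed*
noisy track, min-subtraction offsets the entire clearance series by
the expected minimum of the noise — about $+3.3\sigma$ over a few
thousand flat-foot samples, i.e. +3.3 mm at $\sigma = 1$ mm — which
appears verbatim as Bland–Altman bias. `validate_clearance()`
therefore smooths the marker track (10 Hz zero-phase, configurable)
before normalization, which is standard practice for optical
trajectories. The error metrics take the absolute value (the printed
signed difference is named an *absolute* error and plotted as
all-positive bars); Bland–Altman uses signed differences
$d = x_\text{IMU} - x_\text{OS}$, so negative bias means IMU
underestimation, with limits $\bar d \pm 1.96\,s_d$ (normal-quantile
limits, no small-sample t correction — the conventional presentation).

### Group statistics

Shapiro–Wilk at $\alpha = 0.05$ gates each parameter: if any compared
group rejects normality, all comparisons of that parameter use the
two-sided Mann–Whitney U test (exact for $n \le 20$ without ties,
normal approximation with tie and continuity correction otherwise);
otherwise Student's two-sided independent-samples t test (a Welch
option exists). The eight study comparisons are fixed; p-values are
reported raw, with no multiple-testing correction — deliberately, as
the source analyses report per-comparison p-values; users combining
many parameters should correct externally. Group aggregation uses
per-subject means, avoiding stride-level pseudo-replication.

## The synthetic world

`generate_trajectory()` builds a continuous, twice-differentiable model
of one foot:

- **Stationarity**: the foot is motionless from each heel strike to the
  following heel off, which strictly contains the detected flat-foot
  interval, so ZUPT's zero-velocity assumption is exactly true.
- **Horizontal advance**: one quintic smoothstep (zero velocity *and*
  acceleration at both ends) per cycle from heel off to the next heel
  strike, advancing exactly `stride_length_m`.
- **Vertical profile**: piecewise quintics through the flat-foot
  baseline and the three clearance landmarks at 25%, 55% and 85% of
  swing, returning to baseline at the next toe strike. Knots have zero
  first and second derivatives, so each landmark is a genuine local
  extremum with exactly the stated value. The trajectory is C² but not
  C³ at the knots; finite-difference oracles must step between knots.
- **Angular velocity**: a sum of compact C² bumps
  ($64u^3(1-u)^3$ on its support) — stance humps at HS (120 °/s) and
  TO (200 °/s) and a dominant opposite-signed mid-swing lobe
  (400 °/s) supported on the central 70% of swing so it does not
  displace the stance peaks. Hump widths are calibrated at
  construction time so that, *after* band-limiting, the 30 °/s
  crossings land on the nominal phase boundaries.
- **Orientation**: a bounded sagittal pitch profile (plantarflexion
  about −55° around push-off, dorsiflexion +20° in late swing, zero on
  flat foot) carried by the quaternions. The accelerometer is exactly
  consistent with this orientation. The gyroscope template is *not*
  the exact derivative of the pitch profile: making it so while
  keeping the event morphology would force zero net rotation per
  cycle, which (verified empirically) widens the swing lobe until it
  swallows the stance peaks. The pipeline never cross-integrates the
  two streams, so the inconsistency is invisible to everything tested;
  it is the one deliberate physical compromise in the generator.

**Ground truth is measured, not asserted.** The emitted gyro channel is
band-limited with the same zero-phase response the analysis applies,
and truth events are read off the twice-filtered template at 10×
oversampling — exactly the signal the pipeline sees after its own
filtering. Band-limiting shifts the realized events a few hundredths
of a second from the nominal construction geometry (the realized
phase split for the healthy defaults is ≈ 8.6/35/11.5/45% against
nominal 10.5/40/14.5/35%), just as a real 3 Hz-filtered pipeline
shifts events relative to the underlying biomechanics. Recovery
criteria compare the pipeline with this measured truth; spatial truth
(stride length, landmarks) comes from the analytic trajectory and is
independent of the pipeline's code path.

`simulate_imu()` adds white noise (defaults: gyro 2 °/s, accel
0.05 m/s², typical consumer-MEMS in-band figures) and an optional
constant accelerometer bias used by the drift experiments;
`simulate_markers()` adds white positional noise (1 mm, typical
optical residual) on the shared time base. All randomness flows from
the single seed in the parameter object.

### The cohort generator

`generate_cohort()` draws subject-level parameters for HC (n = 20) and
the four patient subgroups (n = 15 each; the pooled PDoff/PDon groups
are unions, as in the study design). Group means follow the reported
directionality — patients: longer midstance, shorter loading response
and swing, reduced stride length and foot elevation; freezers most
affected; medication partially restorative — with magnitudes chosen
once from the Parkinson's gait literature (e.g. SL 1.30 m HC vs
0.90 m FOGoff, SD 0.15 m; clearance maxima reduced by 20–30 mm).
Between-subject SDs: 0.08 s (ST), 1.5 pp (phases), 0.15 m (SL), 12 mm
(clearance). Two realizability constraints of the band-limited world
are enforced: loading-response and pre-swing durations are floored at
~80 ms (a 3 Hz-limited signal cannot fall from its stance peak below
30 °/s faster), and hump amplitudes are auto-raised for sharp phases
(a shorter phase is physically a stronger pulse).

### What a green test does and does not establish

The generator emulates: periodic stride cycles with four phases,
correct event morphology, flat-foot stationarity, double-humped swing
clearance, sensor noise and slow bias, and group structure. It does
not emulate: stride-to-stride biological variability within a trial
(cycles are identical up to noise), turning, gait initiation or
termination dynamics, freezing episodes (excluded from the analyzed
trials by design), 3-D out-of-sagittal rotation, magnetometer or
quaternion-estimation error, or soft-tissue artifact. Green recovery
tests therefore establish algorithmic correctness under the model's
assumptions — not clinical validity on real recordings.

## Numerical choices and degenerate inputs

Trapezoidal integration throughout (the error is far below the stated
tolerances at 100 Hz for band-limited signals). Threshold crossings
count the boundary sample. Peak search uses prominence with a greedy
minimum-distance rule, highest peaks first; plateau maxima take the
first plateau sample. Degenerate inputs raise classed conditions
(`freezekin_no_strides`, `freezekin_zupt_impossible`,
`freezekin_gate`, ...): all-zero signals, single peaks, missing
flat-foot intervals, constant statistical samples, groups smaller than
three. Strides failing any rule are excluded and logged, never
repaired.

## Known limitations

- Sensor-point clearance, not true foot-lowest-point clearance (no
  foot-geometry correction).
- The Min clearance landmark inherits the largest integration
  systematics (~2–4 mm here), mirroring its reduced reliability in
  optical-vs-IMU comparisons.
- The normality gate is conservative (any group rejects ⇒
  non-parametric), and raw p-values are reported without
  multiple-testing correction.
- Bout boundaries must be supplied; turning detection is out of scope,
  as is freezing-episode detection.
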
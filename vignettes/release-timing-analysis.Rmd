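---
title: "Solution spaces and release timing in virtual throwing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solution spaces and release timing in virtual throwing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skittler)
```

## The task and its physics

The virtual skittles task is a planar throwing game: a player rotates a
lever (length 40 cm, pivot 150 cm below the workspace origin) and
releases a ball that must pass around a central post (radius 25 cm) and
hit a small target on the far side. Once released, the ball behaves as
if attached to two orthogonal massless springs with rest position at
the origin, giving the closed-form flight

$$x(t) = A_x \sin(\omega t + \varphi_x)\, e^{-t/\tau}, \qquad
  y(t) = A_y \sin(\omega t + \varphi_y)\, e^{-t/\tau},$$

an ellipse that decays toward the origin. The natural frequency
$\omega$ and damping constant $\tau$ are task parameters; the
amplitudes and phases follow from the lever state at release by
matching $x(0)$ and $\dot x(0)$ per axis:
$A\sin\varphi = x_0$, $A\omega\cos\varphi = v_0 + x_0/\tau$. A
motionless axis is assigned $A = 0$, $\varphi = 0$ to keep the map
total.

Two execution variables — release angle and release angular velocity —
therefore fully determine a throw. The performance error is the minimum
distance between the flight path and the target centre over one full
oscillation period, with the flight truncated at the first post contact
(centre distance below post radius + ball radius). A throw with error
below 1.1 cm is a hit; below 2.5 cm it still grazes the target
("near"); post contacts and errors beyond the 40 cm display range are
invalid.

Numerical choices: the minimum is located by a 1 ms coarse scan of the
closed form followed by golden-section refinement (default resolution
10^-6^ s; the scan uses rotation recurrences, so scoring a full
execution-space grid takes seconds). The post-contact time is resolved
by bisection and then snapped down to a fixed 0.01 ms grid, which makes
the truncation boundary — and hence the error of post-hitting throws —
a well-defined quantity rather than an artifact of scan resolution.
Setting `post_radius = 0` removes the post entirely. A flight horizon
of one period $2\pi/\omega$ is used because the damped orbit spirals
into the post region; a single period covers the one meaningful
approach to the target.

## Solution space and manifold

`solution_space()` evaluates the error over a release angle × velocity
grid (default 300 × 300 over 0–180° and 0–1000 deg/s; plotted ranges
are display choices, and all statistics are invariant to them beyond
cell-size effects). The solution manifold — the sub-threshold set — is
stored as per-angle velocity intervals rather than a polyline because
several geometries have more than one solution branch per angle.
`velocity_sensitivity()` reports the per-angle coefficient of variation
of error across velocity (post-hit cells excluded; the mean is floored
at 10^-6^ cm so columns with identically vanishing error read as
insensitive rather than as 0/0).

Four representative variants are bundled. Their defining geometric
roles, in execution space:

* **U-Shape** (target (0, 90) cm, clockwise): a symmetric valley with a
  steep error gradient — the hardest variant.
* **J-Shape** (target (20, 40) cm, clockwise): a curved valley that
  terminates against the post-hit region.
* **Box-Shape** (target (25, 45) cm, clockwise): the most tolerant
  variant; a manifold-aligned movement affords a ~50 ms timing window,
  and the manifold extends to lower velocities than U or J.
* **I-Shape** (target (0, 110) cm, undamped, counterclockwise): the
  singular control. The target sits at the antipode of the release
  position at 90°, and an undamped orbit passes exactly through the
  antipode of its release point at $t = \pi/\omega$ regardless of
  velocity, so error does not depend on release velocity and the
  manifold is a band parallel to the velocity axis.

These geometries were chosen by a coarse search over target and post
placements, scored with `space_summary()` (manifold extent, branch
count, post adjacency, edge gradient) until each variant exhibited its
role; they are parameterized in plain YAML (`inst/extdata/configs/`) so
study-specific constants can be dropped in. Two departures from the
common description of the original game are deliberate package design
choices: the Box-Shape here keeps the post centred and is thrown
clockwise, because in this model family displacing the post either
opens a degenerate low-velocity "shelf" (timing windows of several
hundred milliseconds, on which the ideal-release reference is unstable)
or destroys the long-window property; the chosen geometry preserves
the property that actually matters — the longest, steadily growing
timing window of the four variants.

## Timing error and timing window

A recorded arm trajectory (lever angle at 1 kHz with a marked release
sample) is converted to an *error trajectory* by scoring every sample
as a hypothetical release. Angular velocity at each sample uses the
same estimator as at release — the OLS slope of the 20 samples strictly
preceding the sample — so the error at the release sample reproduces
the throw's scored error bit for bit. (Whether instantaneous or
fitted velocity is used for non-release samples is an open choice;
recorded velocities can be supplied directly, and the trailing fit is
the default for consistency. The first 20 samples inherit the first
defined estimate.)

Two per-throw measures are defined on the error trajectory:

* **Timing error** (ms): distance in time from the actual release to
  the ideal release. Three reference rules are provided.
  `nearest_crossing` (default): the error minimum of the sub-threshold
  run nearest the release, falling back to the global minimum when the
  trajectory never crosses the manifold. `global_min`: the global
  minimum. `window_midpoint`: the centre of the selected run — the
  release point that maximizes tolerance to timing noise.
* **Timing window** (ms): the number of sub-threshold samples in the
  run containing the selected reference, times the sampling interval;
  0 when no sample is sub-threshold. Only the segment near the ideal
  release counts when the trajectory crosses the manifold twice. No
  sub-sample interpolation is attempted: values are reported at the
  1 kHz measurement resolution.

On long, flat error valleys the within-run *minimum* is a fragile
reference — trial-to-trial noise moves it anywhere inside the run,
inflating nearest-crossing timing errors for exactly the best-aligned
movements — whereas the run itself (and hence the window and the
midpoint) is stable. This is why the synthetic cohorts below place
releases at, and measure timing error against, the window midpoint.
The timing-window invariant "non-decreasing in the success threshold"
holds within a reference basin; across thresholds the selected run can
switch to a nearer, newly sub-threshold basin, so the property is
tested on single-basin series.

Both measures are invariant under re-parameterizing execution in
Cartesian velocity components $(v_x, v_y)$: the velocity vector
determines the release state up to the rotation sense, so the same
physical launches occur at the same times and every derived time
statistic is unchanged. `timing_measures_by_frame()` computes both
frames side by side; samples with exactly zero velocity keep their
polar representation (the Cartesian frame is undefined there), and the
per-sample rotation sense disambiguates brief counter-rotation.

## The synthetic practice generator

No public recordings of this task exist, so the package ships a
generator whose defaults emulate a multi-day practice study: 4 groups
(one per task variant) × 10 subjects × 6 days × 240 throws/day in 4
blocks of 60.

A single throw is a minimum-jerk lever rotation
$\theta(s) = \theta_s + \Delta\theta\,(10 s^3 - 15 s^4 + 6 s^5)$ over
movement time $T$ (peak speed $1.875\,|\Delta\theta|/T$ at mid
movement), held at the final angle for a follow-through of 0.25 T, and
sampled at 1 kHz. Trial-to-trial variability is Gaussian: release-time
jitter (the quantity the timing measures are designed to recover),
end-angle amplitude noise (default SD 1.2°), and duration noise
(default SD 20 ms). Every throw draws its own sub-seed derived from
(seed, day, throw) by a 31-bit multiplicative mix, so cohorts are
exactly reproducible and trivially parallel.

`calibrate_strategy()` searches start/end angle and movement time so
the noiseless trajectory overlaps the manifold: candidates place the
minimum-jerk velocity peak on manifold points over a range of
amplitudes, the best candidate is refined by coordinate search, and
the planned release is reset to the trajectory's own ideal sample.
Movement times are constrained to 0.12–0.45 s, the range of fast human
single-joint throws; without the cap the search exploits implausibly
slow movements whose windows are limited only by movement duration.

A learner's six days interpolate two schedules chosen to mirror the
two-phase pattern the measures are meant to expose: release jitter
decays geometrically from ~50 ms SD to a per-subject floor of
17.5–19.5 ms (reached by about day 3 — timing error plateaus early),
while the angular misalignment of the strategy decays *linearly* from
~12° to a per-subject floor uniform on 0.4–10° (the timing window
keeps growing through day 6 with no plateau). Movement tempo stays at
the calibrated value throughout, so on the I-Shape — where alignment
cannot lengthen the window without infinite acceleration — the window
stays flat and only the timing error improves. Jitter and alignment
factors are drawn independently per subject, which keeps the two
timing measures from being collinear across subjects (regression VIFs
stay near 1).

Two noise scales are deliberately asymmetric. The per-subject jitter
floors span a *narrow* band: median error and median timing error of a
session are medians over the same 240 jitter draws, so they co-vary
through sampling alone, and a wide spread of true timing ability would
let that shared channel masquerade as a timing-error effect in the
between-subject regressions. The alignment floors span a *wide* band,
and the trial-level execution noise is kept small relative to it, so
that between-subject differences in the timing window — the quantity
late practice is about — stand out from within-session blur.

What the generator does *not* emulate: closed-loop error-driven
exploration (schedules are open-loop), signal-dependent noise,
biomechanical limb dynamics, and fatigue or between-block structure.
Passing tests on synthetic cohorts therefore demonstrate that the
*analysis chain* recovers known generating structure — not that human
learners follow these schedules.

## Session statistics

Per day and subject: success rate (% hits of 240), median performance
error (errors are skewed, so the median characterizes the day), median
timing error, mean timing window. The relative contribution of the two
timing measures to performance is assessed by the standardized
regression $y = \beta_1 x_1 - \beta_2 x_2$ of median error on median
timing error and mean timing window across the subjects of a day; all
three variables are z-scored within day (the between-subject contrast
each panel of such an analysis shows), the fit itself is unconstrained
OLS, and $\beta_2$ is reported as the magnitude entering with the
minus sign. 95% confidence intervals use the t distribution on the OLS
standard errors; the two-predictor VIF $1/(1-r^2)$ diagnoses
collinearity. `late_practice_regression()` pools the last two days
(z-scored within day) for a more stable small-cohort comparison.

On the simulated cohorts this reproduces the qualitative signature of
practice in redundant throwing: timing error falls steeply and
plateaus while the window grows steadily (U, J, Box), late-practice
performance differences are dominated by the window
($|\beta_2| > |\beta_1|$), and the I-Shape control inverts the
ordering, with a flat window and jitter-dominated errors. The test
suite and `scripts/acceptance.R` compute these patterns at full study
scale (10 subjects × 6 days × 240 throws per task); nothing in this
vignette asserts numbers those runs do not themselves produce.

## Degenerate inputs and edge cases

* Zero-amplitude flight axes: $A = 0, \varphi = 0$; a ball released at
  the origin with zero velocity never moves.
* Post contact at the very first instant: the untruncated portion is
  the single release point.
* Error trajectories require ≥ 21 samples (the velocity-estimation
  window); releases are clamped inside the simulated span with ≥ 20
  samples of history.
* An all-post-hit angle column has undefined velocity sensitivity
  (`NA`), distinct from an insensitive column (0).
* Tasks whose target is unreachable have an empty manifold;
  `calibrate_strategy()` refuses them explicitly.

## Limitations

The bundled geometries are representative, not the original task
constants, and absolute magnitudes (success rates, window lengths)
depend on them; only the qualitative contrasts between variants are
design targets. The timing-error reference is ambiguous on wide flat
valleys — documented above and in the generator design. The regression
analysis is descriptive across simulated subjects; inferential
repeated-measures ANOVA machinery is deliberately out of scope, since
standard tools cover it.
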
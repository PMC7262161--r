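---
title: "Methods: home-cage trajectory and laterality analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: home-cage trajectory and laterality analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagetraj)
```

## The measurement chain

A digitally ventilated home cage records a mouse through 12 capacitive
electrodes under the floor, each sampled every 250 ms. Two derived signals
matter downstream:

1. **Activity events.** For electrode $e$ and interval $n$, an event fires
   when $|c_e(t_n) - c_e(t_{n-1})| > \theta$, with $\theta$ a noise
   threshold. Working on the first difference makes the detector exactly
   invariant to per-electrode baseline offsets, which in practice dominate
   between-electrode variation.
2. **Centroids.** The position estimate for interval $n$ is the mean of the
   active electrodes' centres weighted by the magnitude of their capacitance
   change, $\hat p_n = \sum_e w_e \, c^{\mathrm{ctr}}_e / \sum_e w_e$ with
   $w_e = |\Delta c_e|$ over the active set. When no electrode is active the
   position is missing — a gap, never an interpolated value.

Everything else is computed from the centroid track $(t_n, x_n, y_n)$ in cm
and seconds.

## Kinematics

Displacement is the per-step Euclidean distance; speed is the first time
derivative of position along the path, $v_n = d_n/(t_n - t_{n-1})$; and
acceleration the second, $a_n = (v_n - v_{n-1})/(t_n - t_{n-1})$. Quantity
$n$ describes the interval $n{-}1 \to n$, so each series carries a leading
undefined entry, and any entry adjacent to a positional gap is undefined:
derivatives never bridge a gap, which would fabricate motion across dropped
frames.

Two filters are exposed, both with the convention that the printed threshold
is itself the smallest value retained (comparisons are inclusive, $\ge$):

- a minimum-velocity gate for speed summaries, default **0.02 m/s**
  (2 cm/s); configuration accepts m/s and converts, because cage geometry
  and the laterality gate live naturally in cm;
- a minimum-displacement filter for total distance, default 0 cm, to
  suppress apparent movement from sensor jitter when requested.

`resample_regular()` places the track on a regular grid, linearly
interpolating only across gaps no longer than `max_gap` (default twice the
target interval) and never extrapolating. Whether the velocity gate is
applied before or after resampling is not dictated by the method itself; the
package gates on whatever grid it is given, and the pipeline makes the order
explicit in code.

## Turning and laterality

With heading $HE_n$ the direction of the step-$n$ displacement vector
(east = 0°, counter-clockwise positive), the relative turn angle is
$RTA_n = HE_n - HE_{n-1}$ wrapped to $(-180°, 180°]$, and the relative
angular velocity is $RAV_n = RTA_n / (t_n - t_{n-1})$. A step is a **right
turn** when $RTA_n \in [30°, 90°]$ and its own speed is at least 1 cm/s; a
**left turn** symmetrically on $[-90°, -30°]$. The windows are closed on
both ends — an exactly-30° turn counts — and the speed used is the step's
own, since the turn is a property of that step. The laterality index is

$$LI = \frac{R}{R + L} \in [0, 1],$$

undefined (flagged, not zero) when no turn was classified. Angle units are
degrees throughout because the turn windows are stated in degrees; the wrap
convention $(-180, 180]$ makes the boundary case deterministic. The heading
axis convention is arbitrary and all laterality results are invariant to it
up to the mirror symmetry $LI \to 1 - LI$, which the test suite checks
explicitly alongside rotation invariance.

Zero-displacement steps have no heading; an $RTA$ spanning an undefined
heading is undefined and classified `"none"`. The turn windows, speed gate
and displacement filter are all configuration-exposed, since laterality
definitions vary across the literature and tuning them against a given
impairment model is an open question.

Pooling laterality over a day range recomputes $LI$ from the summed $R$ and
$L$ across days (ratio of sums) rather than averaging daily indices: daily
ratios from low-turn days are high-variance and would be weighted equally.
The mean-of-daily mode is available for comparison. Similarly, whether turns
should be pooled per animal-day or per phase first is not fixed by the
method; the default summaries pool per animal–phase–day and both orderings
are reachable from the exported tables.

## Circadian aggregation

Daytime is the lights-on phase, $[07{:}00, 19{:}00)$, nighttime its
complement; the boundaries are half-open so the lights-on instant is day and
the lights-off instant is night (the instant itself is a pure convention).
Samples are assigned to the day index and phase of their end timestamp; day
indices count from a reference midnight (e.g. surgery day = 0), and ranges
printed like "1–7" include both endpoints. "Overall" is computed over the
full 24 h, not as the mean of the day and night summaries, so additive
quantities (distance, activity, turn counts) satisfy day + night = overall
exactly while intensive ones (mean gated speed) need not. Periods with no
data yield missing metrics rather than zeros. Group location and spread are
reported as mean ± SEM with the $n-1$ sample standard deviation; an SEM over
a single animal is flagged undefined.

The long-format export (one row per animal × day × phase × metric, group
attached, keys unique) is the input contract for longitudinal modelling —
GEE or GLM with time and group as fixed effects — which is deliberately left
to dedicated statistics packages; this package prepares the table and stops
there. Both gated and ungated speed summaries can be exported, since which
gating preceded any published model fit is rarely recoverable.

## The simulator

`simulate_path()` is a correlated random walk on the 250 ms frame grid:
per-step heading changes with magnitude from a half-normal (sd 30°) or
uniform distribution and sign positive (rightward) with probability
`p_right`; step lengths exponential with a phase-dependent mean; rest steps
(zero displacement) with probability 0.4 per frame. Defaults emulate a
singly housed mouse: mean moving speed 2 cm/s in the light phase, threefold
higher dark-phase step lengths on a 12 h light/dark cycle starting at
lights-on, in a 35 × 20 cm cage floor tiled 4 × 3 by the electrode grid
(8.75 cm pitch).

Wall confinement is specular reflection implemented incrementally: the walk
runs free until its first wall contact (processed in vectorised chunks for
speed), the offending step's endpoint is mirrored at the wall, the heading
is reset to the realised step direction, and integration resumes. The
obvious shortcut — folding the unbounded cumulative path into the box with a
triangle-wave map — yields identical *positions* for an unbiased walk but
mirrors entire path segments, silently flipping turn handedness about half
the time and destroying any planted lateral bias; the incremental scheme
perturbs chirality only at the rare bounce steps themselves.

`simulate_recording()` is the forward sensor model: capacitance is a
per-electrode baseline plus a Gaussian kernel of the distance from mouse to
electrode centre (gain 100, length scale 6 cm by default) plus Gaussian
noise. Any monotone-decreasing kernel preserves the estimator's invariants;
the Gaussian is chosen for smoothness. The recording's activity threshold
defaults to $\theta = 4\,\sigma_{\mathrm{noise}}$, i.e. events require a
four-sigma excursion of the difference signal, making false positives rare
without suppressing genuine motion. Weighting centroids by $|\Delta c|$
rather than signed change avoids negative weights; whether real hardware
uses magnitude or signed change is not documented publicly, so the choice is
flagged here.

`simulate_cohort()` reproduces the study design — two groups, singly housed,
recorded 24/7 at 250 ms (12 animals per group for 35 days at the defaults) —
with per-animal seeds derived from one master seed and ground truth recorded
per animal, so planted effects on locomotion (step-length multiplier),
activity amplitude (sensor gain multiplier) and laterality (`p_right`) can
be recovered blind.

**What the simulator does not emulate:** thigmotaxis and corner preference,
bedding and nesting artefacts on capacitance, multi-animal occupancy,
grooming/rearing signatures, habituation trends across days, and any
pathology-specific gait change. Passing recovery tests therefore shows the
*pipeline* is unbiased and correctly calibrated on CRW-like motion, not that
any particular biological effect would be detected in real cages.

## Numerical choices and degenerate inputs

- Time is seconds as double; wall-clock anchoring is metadata only, so
  daylight-saving discontinuities cannot corrupt arithmetic.
- Strictly increasing timestamps are enforced at construction; duplicate
  timestamps are reported with their index.
- Activity events use a strict inequality ($> \theta$); an exactly-threshold
  change does not fire. Speed and displacement filters are inclusive.
- A single-sample trajectory has an empty displacement series (not an
  error); an empty trajectory is an error.
- Polar bins partition $(-180°, 180°]$ half-open left / closed right, so
  every wrapped angle lands in exactly one bin and bin counts sum to the
  number of defined angles.
- Estimated centroids are convex combinations of active electrode centres
  and therefore always lie inside their convex hull (and the cage).

## Problem sizes

The test suite and the acceptance script run entirely on simulated data at
desk scale: the null-laterality walk uses $10^5$ steps (binomial standard
error on $LI$ about 0.002 at the realised turn counts), oracle-equivalence
checks use up to 1000-point random tracks against independently coded
brute-force references at $10^{-9}$ tolerance, effect-recovery suites use 20
replicate cohorts of 6 animals at 12 minutes of recording each, and the
frame-count contract is asserted on one full simulated day (345,600 frames
at 250 ms). These sizes were chosen so each statistical check has comfortable
power while the whole suite stays fast enough to run on every change.

## Known limitations

- Centroid accuracy is bounded by the physics of the device: 12 electrodes
  over 700 cm² cannot resolve below a few centimetres, and the
  difference-based weighting under-weights the electrode directly beneath a
  slowly moving animal (its capacitance changes least). Turn statistics from
  sensor-estimated centroids are correspondingly noisier than from the
  ground-truth path, though the laterality index is robust to this (it is a
  ratio of symmetric errors).
- Rest intervals produce no capacitance change and hence no position;
  long rests appear as gaps, which is faithful to the device but means
  per-phase coverage can be uneven.
- Linear interpolation is the only gap-bridging offered; no smoothing or
  spline filtering, no 3-D, no multi-animal tracking.
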
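---
title: "From centre-point trajectories to probing behaviour: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From centre-point trajectories to probing behaviour: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphidtrack)
```

## The inference problem

Aphids feed by inserting their stylets into plant tissue. Long penetration
events ("probes", of 25 minutes and more) are a proxy for successful phloem
access and hence for plant susceptibility; resistant plant lines shorten and
fragment them. The reference method for observing stylet activity is the
Electrical Penetration Graph (EPG), which wires every aphid individually. A
video-tracking alternative scales to ~100 arenas per camera rig but only sees
the aphid's body: on an overhead camera the mouthparts are invisible, so the
method assumes that *an aphid that is on the leaf disc and not moving is
probing*. Everything in this package flows from making that assumption
operational and testing what it can and cannot detect.

The pipeline is:

1. **Kinematics** (`compute_kinematics()`): the 25 fps centre-point track is
   down-sampled to 5 samples/s, speed is the backward finite difference
   between consecutive analysis samples, and the reported speed is a 5-sample
   centred moving average. Each sample is assigned to zone 1 (leaf disc minus
   an edge margin), zone 2 (the rest of the arena) or `undetected`.
2. **Probe detection** (`detect_probes()`): a two-threshold state machine
   with hysteresis and dwell times (below).
3. **Response variables** (`summarize_observation()`, `summarize_bins()`):
   the per-arena screening variables — totals and counts of probes by
   duration category, time not moving, distance moved, per-hour activity.
4. **Validation** (`match_events()`, `accuracy_summary()`): interval-overlap
   matching of automated against manually annotated probes.
5. **Power simulation** (`detection_rate()`): how many replicate arenas are
   needed before a plant-line contrast becomes statistically detectable.

## The probe state machine

A probe **starts** when the subject is in zone 1 and its speed drops below
`v_probe_start` = 0.02 mm/s and does not reach `v_probe_stop` for at least
`t_probe_start` = 10 s. A probe **stops** when speed exceeds `v_probe_stop`
(0.3 mm/s for *Myzus persicae*, 0.35 mm/s for the larger winged *Nasonovia
ribisnigri*) and does not fall below the hysteresis level `v_hysteresis` =
0.1 mm/s for at least `t_probe_stop` = 2 s. The hysteresis band plus the 2-s
dwell absorbs the brief body movements an immobile, feeding aphid still makes
(reproduction, honeydew excretion): a one-second twitch above 0.3 mm/s that
subsides below 0.1 mm/s does not end the probe. Leaving zone 1 force-ends a
probe at the exit sample, since off-disc stillness is not probing.

Numerical conventions, chosen once and tested:

* All comparisons are strict (`<`, `>`); an at-threshold sample never
  triggers a transition. The choice is measure-zero for real data.
* Intervals are half-open `[start, stop)` seconds from observation start;
  probe and non-probe intervals exactly tile the observation (a property the
  test suite checks on random series).
* Samples with undefined speed (tracker dropouts longer than the 1-s
  interpolation limit) never trigger a transition and disqualify any dwell
  window containing them.
* A stillness window truncated by the end of the observation before 10 s
  have elapsed does not start a probe; a probe still open at the end of the
  observation ends there.

**Start-timestamp conventions.** Where exactly does a probe start? The
package backdates it to the beginning of the qualifying stillness window
(`start_at = "onset"`, the default), so probes span the still period. Event
exports of commercial tracking software instead record the state change when
the dwell condition is confirmed (`start_at = "confirmed"`), i.e. 10 s into
the stillness. The difference matters for one artifact: an aphid sitting
exactly on the zone-1 edge makes the assigned zone flicker, chopping one
probe into a train of fragments. Under the onset convention each fragment
spans its own 10-s qualifying window and is therefore never shorter than
10 s; under the confirmed convention fragments of an in-zone dwell lasting
10–13 s come out *shorter than 3 s* — the signature by which such trains are
recognised in practice. `filter_zone_transitions()` removes them: one
left-to-right pass deletes every probe shorter than 3 s whose preceding
non-probe bout lasted at most 15 s, with gaps measured on the unfiltered
stream so that a whole train following a genuine probe is removed (evaluating
against the merged stream would let accumulated gaps exceed 15 s and spare
later train members). A short probe opening the observation has no preceding
non-probe bout and is retained.

**A coupling worth knowing about.** `v_probe_stop` plays two roles: it ends
probes, and it bounds the speeds allowed inside a probe-start window. Raising
it therefore admits *more* probe starts, so the intuitive monotonicity
"higher stop threshold, fewer probe stops" only holds when the start windows
are unaffected; the property tests pin the start windows accordingly.

The moving/not-moving machine (`detect_movement()`) is simpler: moving begins
above 0.3 mm/s, ends below 0.02 mm/s, no dwell times, initial state taken
from the first defined sample.

## Kinematics choices at points the method leaves open

* **Down-sampling 25 → 5 Hz** takes every 5th frame without position
  averaging; position noise is handled by the speed smoothing. Whether the
  original software averaged positions or speeds over the 5-frame window is
  not documented; both are available (`position_average`), the default is
  plain decimation.
* **Velocity estimator**: backward finite difference at 5 Hz, then a
  5-sample centred moving average, shrunk at the series boundaries and
  ignoring undefined neighbours. The first analysis sample has no backward
  difference and contributes no displacement.
* **Dropout policy**: undetected gaps of at most 1 s bounded by detections
  are linearly interpolated so a blink of the tracker does not cut a probe in
  two; interpolated samples keep `detected = FALSE` for the quality-control
  fraction but receive a position-based zone. Longer gaps leave speed
  undefined.
* **Distance moved** counts zone-1 displacements only, following the
  convention that only on-disc behaviour enters the analysis; configurable
  via `distance_zones`.
* **Zone-1 margin**: 0.75 mm by default, turning a 6-mm leaf disc into an
  effective zone-1 diameter of about 5 mm, so that aphids on the disc rim or
  the arena wall are not credited with probing.

## Probe categories and response variables

Categories are duration thresholds on whole probes: short < 3 min,
long ≥ 25 min (inclusive), sustained > 35 min (exclusive), "other" the strict
complement of long. All three are configurable (`probe_categories()`); a
probe can be long and sustained at once. Mean long-probe duration and latency
to the first long probe are reported as missing — not zero — when no long
probe occurred, which matters when averaging across arenas. Per-hour tables
apportion a probe's time to bins pro rata while deciding its category from
its full duration. Quality control excludes observations whose detected
fraction falls below 0.9 (the screening assays discarded a handful of arenas
with poor detection; no numeric cut-off is published, 0.9 is this package's
default and is configurable).

## Validation against manual annotation

Two probes match when their intervals overlap with positive length; touching
endpoints do not count. A manual probe overlapped by two or more automated
probes is *overrated* (the software split it); an automated probe overlapping
two or more manual probes marks them *underrated* (the software merged them).
Start/stop/duration offsets are computed against the overlapping automated
probe whose duration is closest to the manual one, ties broken by earlier
start. Offset confidence intervals are t-based at 95%; the bootstrap agrees
within 20% of the interval width on synthetic offsets (tested). Correlation
tests choose Pearson, Pearson-on-logs or Spearman by a Shapiro normality
screen at α = 0.05, mirroring common practice for these skewed duration
variables.

## Power simulation

`simulate_group()` draws a pool of 10⁴ values from a normal distribution
with a group's mean and SD, **rejecting** draws below the variable's lower
bound (zero, or the probe-category minimum — 25 min for the mean duration of
long probes) or above the recording duration (480 min), and redrawing until
the pool is full, so the pool size is exact. Specifications whose truncation
keeps less than 1% of the mass are refused. Pool moments match closed-form
truncated-normal moments within Monte Carlo error (tested).

`detection_rate()` subsamples each pool without replacement, `n` replicates
per group per iteration (1000 iterations), runs an equal-variance Student's
t-test per variable (Welch via `var_equal = FALSE`), and calls an iteration
significant when any variable's p-value falls below the Bonferroni-corrected
α = 0.05/2 = 0.025. The two simulated variables are drawn independently — no
correlation structure between response variables is published; this makes
the familywise null rate exactly 1 − (1 − α)² ≈ 4.94%, which
`type1_rate()` reproduces (both null groups are disjoint subsamples of one
shared pool). Because all iterations share the same pools, the Monte Carlo
error of a rate has a between-pool component on top of the binomial one; the
test suite propagates it where it matters.

The shipped presets (`arabidopsis_video_specs()`, `lettuce_video_specs()`)
encode the published video-tracking group summaries of the two case studies
(resistant vs susceptible plant line, two probing variables each). The
published tables print standard errors, so group SDs are **derived** as
SE·√n with the printed per-variable n; the original simulation parameter
table is not available in the supplementary material we can access, and the
presets are documented as derived. `duration_rescale()` emulates shorter
recordings by scaling mean, SD and upper bound by the duration ratio,
keeping the lower (category) bound; the policy is pluggable because the
original rescaling procedure is not described.

## The synthetic-data generator

`generate_schedule()` builds bout sequences — walking, probing, edge-dwelling
— with exponential durations (means: walks 60 s, probes 1800 s, weights
0.5/0.5, no edge dwells unless requested), which makes an 8-h schedule
probing-dominated, as aphids on a susceptible host are. Confounding spikes
(0.6 s, 0.5 mm/s peak, one per ~10 min of probing) emulate the brief body
movements that the hysteresis rule must absorb. `render_trajectory()` turns
the schedule into a 25-fps track: correlated random walks confined to the
zone-1 interior, probing as a fixed anchor plus Gaussian jitter of 0.8 µm per
frame — chosen so the smoothed pseudo-speed of a probing aphid stays well
below the 0.02 mm/s start threshold (≈ 0.008 mm/s at the 99th percentile),
because probing must register as stillness for the proxy to make sense.
True aphid centroid jitter during probing is unpublished; these values are
illustrative. Edge dwells anchor the apparent position 5 µm inside the zone-1
boundary with a slow drift (SD 6 µm, correlation time 2 s), which makes the
assigned zone alternate in dwells of seconds and reproduces the probe-train
artifact.

`render_frames()` rasterises background, leaf disc and an elliptical subject
(1.7 × 0.8 mm, oriented along the heading) with area-coverage anti-aliasing,
and `track_frames()` closes the loop: per-zone grey thresholds, largest
8-connected component, binary pixel centroid (ties: darker mean grey, then
top-left). Connected-component labelling is done in-package because the
available image library labels 4-connected components. Round-trip centroid
error is below 0.5 px RMS (tested).

What the generator does *not* emulate: body-posture changes that move the
centroid without locomotion, lighting gradients and shadows, occlusion at
the arena wall, multi-aphid scenes, and realistic leaf texture. Passing the
recovery tests therefore shows the event logic and the tracker are correct
given the model's assumption — stillness equals probing — not that the
assumption holds on any particular real video.

## Problem sizes used in the tests

The suite exercises the state machines against a naive per-sample reference
automaton on 10⁴ random threshold-crossing series, recovers scheduled
probing through the trajectory-level loop on a 4-h observation with true
25-min categories, and through the full frames loop on a 90-s observation
with proportionally shortened categories and 128-px frames — frame rendering
at 25 fps makes multi-hour stacks pointless when the logic under test is
scale-free. Power results use the full published protocol (10⁴-draw pools,
1000 iterations).

## Known limitations

* The stillness-equals-probing assumption undercounts probing interrupted by
  grooming-free stillness off the disc and cannot distinguish phloem
  ingestion from, e.g., xylem drinking; long probes are a proxy, not a
  waveform measurement.
* With the onset timestamp convention the detector cannot emit sub-10-s
  probes, so the 3-s/15-s filter is only active on event streams produced
  under the confirmed convention (or imported from other software).
* Derived preset SDs (SE·√n) reproduce the published group dispersion only
  insofar as the printed n matches the simulated variable's n.
* The minimal blob tracker assumes exactly one subject darker than both
  zone thresholds; it is a validation instrument for the synthetic loop, not
  a replacement for a production tracker.
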
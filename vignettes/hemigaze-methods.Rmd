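---
title: "Simulating hemianopia on a panoramic rig and analysing driving gaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating hemianopia on a panoramic rig and analysing driving gaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemigaze)
```

## The problem

Homonymous hemianopia — loss of the same lateral half of the visual field in
both eyes — can be emulated in a driving simulator with a gaze-contingent
display: an occluding overlay that follows the driver's gaze in real time and
masks everything left (LHH) or right (RHH) of the current gaze direction.
`hemigaze` is an offline toolkit around such a setup on a panoramic rig of
three 3400×2720-pixel panels spanning a 180° frontal field of view, with
60 Hz gaze tracking and 240 Hz driving data. It covers three concerns:

1. **Mask replay** — mapping gaze direction vectors to panel pixel anchors
   and reproducing the mask update loop (buffering, large-movement bypass,
   hold-on-signal-loss, semitransparent fade) offline, for latency and
   coverage diagnostics.
2. **Gaze and driving analysis** — the processing chain from raw 60 Hz gaze
   streams to per-intersection scanning and lane-keeping metrics, including
   the equal/above/below (EAB) within-subject comparison.
3. **Synthetic studies** — a generator that emulates a full
   15-subject × {NV, LHH, RHH} × {SCI, LTI, RTI} design with planted ground
   truth, so every pipeline stage is testable without recorded data.

## Mask geometry and anchor dynamics

Gaze direction is a unit vector from the virtual eye position (z forward,
x rightward, y upward); azimuth is `atan2(x, z)` with negative values to the
left, elevation `asin(y)`. Each flat panel is tangent to a circle centred on
the eye and subtends 60° of azimuth; panels own the half-open sectors
[−90°, −30°), [−30°, 30°) and [30°, 90°], a deterministic tie-break that
gives +30° to the right panel. Within a panel,
`px_x = W/2 · (1 + tan(az − centre)/tan 30°)`, and the vertical half-angle
follows from the pixel aspect ratio, `atan((H/W)·tan 30°) ≈ 24.8°`. The
pixel origin is top-left; anchors are kept at fractional pixels.

The anchor is stabilised by a moving average over the last 3 valid azimuth
samples (~50 ms at 60 Hz). Two exceptions keep the mask honest during
dynamic scanning:

* **Bypass**: a movement larger than 10° relative to the previous output is
  passed through unsmoothed *and resets the window*. Without the reset, the
  anchor would snap back toward the pre-step mean on the following frame;
  with it, any step beyond the threshold is tracked in exactly one sample.
* **Hold**: an invalid sample leaves the anchor at the last valid output and
  sets a `held` flag; `lag_samples` counts frames since the last fresh
  anchor.

The mask opacity falls linearly from 1 to 0 over a configurable fade width
centred on the anchor (default 4° of visual angle; the fade is specified in
visual angle rather than pixels so that its retinal size does not depend on
the panel the gaze happens to be on). The occluded fraction of the frontal
field has a closed piecewise-linear integral; with the ramp fully inside the
field it equals the hard-edge value, e.g. `(anchor + 90)/180` for a left
mask — a convenient diagnostic invariant.

Buffer length, bypass threshold and fade width are configuration keys with
declared defaults: they are properties of a deployment, not measured
constants.

## Gaze preprocessing

The pipeline order is fixed: head-pose fallback → region exclusion →
low-pass filtering.

* **Fallback**: invalid eye samples take the head-pose-derived azimuth,
  which is less accurate but more stable; samples lacking both carry the
  last usable azimuth and are marked `held`.
* **Exclusion**: blinks and gazes to mirrors, the media system or other
  non-driving areas are flagged and removed from event detection and all
  statistics, but still advance time — gaps are never interpolated, because
  interpolation would fabricate gaze positions inside blinks.
* **Filtering**: an order-2 Butterworth low-pass at 10 Hz, applied
  forward–backward (zero-phase) per contiguous unexcluded segment. Offline
  analysis tolerates non-causal filtering, and a one-way filter's group
  delay would bias fixation onsets. Segments shorter than 5 samples pass
  through unfiltered. Segment ends are padded by odd reflection before
  filtering; without that padding, a segment ending away from zero azimuth
  sees an artificial step at its boundary that injects spurious
  high-velocity transients. The implemented digital (bilinear) filter has
  the exact zero-phase gain `1/(1 + (tan(πf/f_s)/tan(πf_c/f_s))^4)`,
  which the tests verify at 2 Hz (pass-band) and 20 Hz (stop-band).

## Event detection

Fixations use a dispersion–duration rule with a conjunctive velocity check,
in the style of the ISO 15007 recommendations: a window of at least 120 ms
whose horizontal positions span ≤ 2° and whose sample speeds (central
differences on the filtered azimuth) stay below 30°/s, extended rightward
while both conditions hold. Each sample is treated as covering one frame
period, so a 1 s plateau of 60 samples yields a duration of exactly 1.0 s.
Saccades are maximal runs of samples at ≥ 90°/s; amplitude is the absolute
azimuth displacement between the run's first and last samples, direction its
sign, and the endpoint azimuth is kept for the directional analysis. Samples
between 30 and 90°/s belong to neither class. Excluded samples terminate
events of both kinds. Dispersion is measured on the horizontal azimuth only,
matching the lateralised question the masks pose.

A consequence worth knowing: after the 10 Hz filter, the one or two samples
flanking each saccade carry smeared transition velocity in the 30–90°/s dead
zone. They are excluded from the fixation, so detected fixation durations
run about two frame periods (~33 ms) below the true dwell time, regardless
of how sharp the underlying saccade was. Detected saccade amplitudes are
essentially unbiased for amplitudes above ~15°, while amplitudes below ~10°
are strongly truncated because the filtered velocity barely clears the
90°/s threshold. Both effects are properties of the measurement chain, not
implementation artefacts; the parameter-recovery checks document them (see
*Synthetic studies* below).

## Scenario metrics

An intersection approach is segmented into its **deceleration phase**: from
the first brake activation found within 100 m of the intersection to the
moment distance reaches zero at the zebra crossing; if the brake is never
pressed in that zone, the window starts at 41.76 m (the printed constant for
a 3 s deceleration onset at 50 km/h, retained as printed even though
3 s × 50 km/h is 41.67 m). Gaze (60 Hz) and driving (240 Hz) streams are
aligned by timestamp and clipped to the closed window.

Within the window the package computes: mean and sample variance of the
lane-centre offset (cm) and the number of entries into the region beyond a
lane boundary (default 85 cm = (3.5 m lane − 1.8 m vehicle)/2, a
configuration key since the deployment's exact geometry is a scene
property); the side of the first gaze beyond 30° and beyond 45°; flags for
missing large (≥ 45°) scans per side; horizontal gaze variance, mean,
minimum and maximum; fixation counts and mean durations per hemispace
(beyond the central 10°, i.e. |azimuth| > 5°; central fixations count to
neither side); and mean saccade amplitudes per direction, counting only
saccades whose endpoint lies more than 5° into the target hemifield.
`aggregate_metrics()` emits model-ready condition × intersection summaries
and count tables with percentages rounded half-up to two decimals.

## The EAB comparison

Because individual differences dominate in small driving samples, the EAB
analysis classifies each subject's impaired-condition value against their
*own* normal-vision value: the band is the subject's NV value ± half the
interquartile range of all participants' NV values in the same intersection
type; values inside the closed band are *equal*, otherwise *above* or
*below*. Three details are deliberate choices, configurable where sensible:
the quantile estimator is type 7 (linear interpolation of order statistics,
the common default; small samples make the choice visible, so it is a
parameter), the band bounds are closed, and the subject's own NV value stays
in the reference sample. A modified form compares the blind-side fixation
count against a band of the seeing-side sample centred on the subject's
seeing-side count. For lane position, `buffer_table()` translates the
classifications into blind-side/seeing-side buffer counts: a rightward shift
buffers the blind side under LHH, a leftward shift under RHH.

## Synthetic studies

`generate_study()` builds the full 15 × 3 × 3 design: per scenario a 240 Hz
driving trace (cruise at 50 km/h, uniform deceleration from a randomised
brake-onset distance to a residual crossing speed, AR(1) lane offset; a
small fraction of straight-crossing NV approaches never brake and exercise
the fallback rule) and a 60 Hz gaze stream whose duration matches the
approach.

The scanpath generator is built for *recoverability*: every planted quantity
is laid out so the detection chain can, in principle, read it back.

* Fixation durations are shifted-lognormal (shift 0.15 s) with the profile's
  exact arithmetic mean and SD; positions follow a reflecting random walk in
  a ±36° box centred on the profile's gaze bias, which makes the stationary
  mean equal the bias by symmetry.
* Saccade amplitudes are drawn from a normal truncated to [5°, 75°] whose
  location is solved so the truncated mean equals the profile mean.
  Transitions are constant-velocity ramps on the sample grid (~600°/s, near
  the representable limit at 60 Hz) whose endpoint samples sit exactly on
  the flanking fixation positions — so the 10 Hz filter, not the generator
  kinematics, determines what the detector sees. Physiological saccades are
  slower and minimum-jerk-shaped; that realism was traded away because any
  slower kinematics push a sizeable share of each saccade's displacement
  below the 90°/s threshold and make the planted amplitudes unrecoverable
  in principle.
* Large-scan behaviour is planted explicitly: with the profile's per-side
  probability, an excursion drives the walk beyond 50° and back. Central
  positions stay at ≤ 40° and are snapped out of a 27.5–32.5° guard band,
  so the 30° and 45° criteria are never decided by noise or filter
  overshoot, and categorical truths (first-scan side, missing-scan flags)
  are exact in the noise-free setting.
* Degradations are injected at profile rates: 0.3° Gaussian position noise,
  blinks (6/min, 150 ms, eyelid-frozen signal, labelled in the AOI channel
  — deliberately below resting blink rates, reflecting blink suppression
  under high visual demand), and tracker dropouts (2% of samples in short
  runs). The head-gaze channel is the eye azimuth plus a slowly drifting
  AR(1) error (2° SD, ~1 s correlation): stable but inaccurate, which is
  the property the fallback stage relies on.

Condition profiles default to the reported direction of effects — longer
fixations and smaller amplitudes under LHH, a rightward bias under RHH,
fewer large scans under LHH on both sides — with magnitudes chosen as
plausible free parameters, not as reproduction targets.

**What passing tests show, and what they do not.** Recovery of planted
truths demonstrates that the pipeline implements its stated rules
correctly. It does not show that the generator reproduces human scanning:
real gaze has smooth pursuit, vergence noise, head-coupled dynamics,
main-sequence kinematics and compensatory strategies that this generator
deliberately omits. Two recovery results are worth stating plainly, at the
n = 200 events per condition used by the checks: saccade-amplitude means
and gaze bias are recovered within three standard errors, while detected
fixation-duration means run 30–60 ms below the planted means — the
plateau-edge shaving described above, aggravated by blink-induced
fragmentation of long fixations — and fail a three-standard-error check.
We report that bias rather than calibrating the generator to hide it.

## Numerical choices and degenerate inputs

* Percentages are rounded half-up to two decimals; a zero denominator gives
  a missing value.
* A gaze window with fewer than two usable samples yields missing summary
  statistics; an empty saccade or hemispace class yields a missing mean,
  never zero.
* All-invalid gaze histories anchor the mask at the rig centre with a
  warning; azimuths outside ±90° clamp to the field edge and are flagged.
* Filter segments shorter than 5 samples pass through unfiltered; a cutoff
  at or above Nyquist is a configuration error caught before any
  computation.
* Every random quantity flows through an explicit seed; scenario seeds are
  derived deterministically from the master seed and stay below 2³¹.

## Problem sizes

The bundled checks run the full 135-scenario synthetic study once at
default noise and once noise-free, 10⁵-point mask round-trips, 1000-trace
detector-oracle comparisons, and 200-event-per-condition recovery — sizes
chosen so the whole suite completes in a few minutes on one core while
keeping Monte-Carlo standard errors well below the tolerances they guard.

## Known limitations

* The fixation-duration measurement bias above affects any analysis that
  compares absolute durations across processing chains; within-study
  condition contrasts are unaffected because the bias is common to all
  conditions.
* Real-time integration (tracker, projector compositing) is out of scope;
  the mask engine replays logs.
* Lane-position variance units depend on the configured offset units;
  cross-study comparisons of variance magnitudes need care.
* The EAB band construction for the blind/seeing variant is one reasonable
  reading of a loosely specified procedure; the quantile type and band
  closure are parameters so sensitivity is easy to check.
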
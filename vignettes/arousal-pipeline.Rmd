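---
title: "From wrist-worn biosensor sessions to incident-aligned arousal inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wrist-worn biosensor sessions to incident-aligned arousal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e4arousal)
```

## The scientific problem

Children admitted to psychiatric care for severe behavioral problems show
episodes of disruptive and physically aggressive behavior whose
psychophysiological signature — a rise in sympathetic arousal — may be
measurable with a wrist-worn biosensor worn during normal daily activities.
The measurement setting is hard: the device is worn by active children for
days at a time, the signal is riddled with motion artifacts and off-wrist
stretches, behavior is coded by staff at minute resolution with a
traffic-light scheme (green = good behavior, orange = disruptive behavior,
red = physical aggression / severe disruption), and arousal varies strongly
with the time of day (meals, school, sports, therapy).

This package implements the full analysis chain for that design: raw
multi-channel sessions in the standard per-channel CSV export layout (EDA at
4 Hz in µS, skin temperature at 4 Hz in °C, triaxial acceleration at 32 Hz
in 1/64-g counts, blood volume pulse at 64 Hz, device-derived HR at 1 Hz,
sparse inter-beat intervals), quality masking, derived arousal measures,
5-minute incident frames paired with within-person references matched on
clock time, and a Bonferroni-corrected family of paired *t* tests on four
measures: movement (g), HR (bpm), tonic skin conductance level (SCL, µS) and
skin-conductance-response peaks per minute (PPM).

## The inference design

The core procedure is built around within-person, time-of-day-matched
comparison:

1. **Incident frames.** Every red (physical aggression) observation anchors
   a 5-minute frame starting at its recorded time. Red events that start
   within one merge window (default 300 s) of an already-anchored incident
   are folded into that frame so a single escalation is not double-counted.
2. **Reference frames.** For each incident, the windows at the *same local
   clock time* on the participant's other wearing days are candidate
   references. This controls both the person (all comparisons are
   within-child) and the daily routine (10:05 is compared with 10:05).
3. **Exclusions.** A candidate reference is dropped when any aggression
   observation overlaps its window (the event's ±1-minute timestamp
   uncertainty counts as overlap, and the overlap set defaults to red and
   orange events — the conservative choice, configurable to red-only), and
   any frame — incident or reference — is dropped when more than 75% of its
   EDA epochs are artifact or off-wrist. The boundary is strict: a frame at
   exactly 75% is retained.
4. **Pairing and inference.** Each usable incident contributes one pair:
   its value against the mean of its retained references, per measure. The
   family of four paired *t* tests is evaluated at the Bonferroni-adjusted
   level 0.05/4 = 0.0125 (reported as .013).

The pairing unit is the incident, not the participant: the published
degrees of freedom (32 on 54 recorded incidents, after exclusions) are only
consistent with incident-level pairs, so that interpretation is built in.
Children contribute as many pairs as they have usable incidents;
between-incident dependence within a child is a known limitation (see
below), accepted here to mirror the original exploratory analysis rather
than replace it with a mixed model.

## Quality masking

Wearable EDA needs screening before anything else is computed. The package
uses transparent epoch-level rules (5-second epochs), in the spirit of the
widely used wearable-EDA screening tools:

* **range** — any sample below 0.05 µS or above 60 µS (an EDA of exactly 0
  is the classic off-wrist signature, which is also why missing data are
  explicit `NA`s and never encoded as 0);
* **slope** — an absolute sample-to-sample rate of change above 10 µS/s,
  faster than any physiological skin-conductance change;
* **temperature** — skin temperature below 30 °C, i.e. no skin contact.

Epochs where any rule fires are artifacts; maximal artifact runs lasting at
least 10 minutes (600 s) are relabeled *off-wrist* — prolonged absence of
valid signal means the device was probably not worn. The distinction
matters twice. First, retention accounting is staged (raw hours → hours
after removing long noise → hours after also removing artifacts, with
percent reductions at each stage). Second, the device keeps emitting a
plausible-looking but artificially high heart rate while off the wrist, so
off-wrist spans are used to blank HR; without that step, off-wrist HR
contaminates both day-level HR distributions and frame summaries. A
machine-learning artifact classifier is deliberately not included: the
rules are the contract, they are individually configurable
(`pipelineConfig()`), and their behavior is checkable against brute-force
evaluation.

## Derived measures

* **SCL** is the 30-second centered moving average of raw EDA over *valid
  samples only*; positions whose window holds no valid sample are missing.
  The moving average stands in for heavier filtering — on this kind of
  data it tracks a filtered signal closely while staying transparent.
* **Phasic EDA** is raw minus SCL. **SCR peaks** are trough-to-peak events
  on the phasic component with rise amplitude ≥ 0.05 µS, rise time
  ≥ 0.25 s, and ≥ 1 s separation; peaks inside artifact/off-wrist epochs
  are discarded. **PPM** divides the peak count by *valid* minutes, so
  artifact time does not deflate the rate (`features.ppm_denominator`
  switches to wall minutes for sensitivity analysis).
* **Movement** is the Euclidean norm of acceleration with the static
  gravity component removed by subtracting a 60-second moving median of the
  norm, rectified, averaged to a 1-second grid. At rest the norm sits at
  1 g and movement is ~0; an oscillation of amplitude *A* riding on gravity
  yields mean movement 2A/π, which is the closed form the tests check.
* **HRV (RMSSD)** is computed from inter-beat intervals, in ms, using only
  successive differences between intervals the device marked consecutive
  (the offset gap between adjacent rows equals the later interval within
  20 ms); differences are never taken across detection gaps. Windows with
  fewer than 10 successive pairs are missing. Because optical inter-beat
  detection fails under motion, valid IBI coverage in active children is
  sparse: RMSSD is displayed on the dashboard but excluded from inference.

## The synthetic cohort

No clinical recordings ship with the package; a seeded generator
(`generateCohort()`) emulates the study inputs end to end, and its defaults
*are* the study conditions: 30 children (18 clinic, 12 daycare; ages 6–14)
wearing the device for 5 consecutive weekdays, clinic 08:00–20:00 and
daycare 08:00–15:00 local time; HR baselines drawn inside the pediatric
norm bands (80–120 bpm for ages 6–12, 60–100 bpm for ages 12–14); red
incidents at 0.36 and orange at 1.74 per child-day (the published 54 and
261 events over 150 child-days). Signals are built from standard
components: tonic EDA with slow sinusoidal drift (amplitude 0.8 µS, period
3 h) plus phasic responses as a Bateman kernel (0.75 s rise, 3 s decay) at
Poisson times (2.6/min, lognormal amplitudes); HR as a stationary AR(1)
(ϕ = 0.97 at 1 Hz, marginal SD 6 bpm) around the child's baseline;
acceleration as rest noise plus movement bursts; skin temperature near
33 °C on-wrist. Off-wrist episodes (probability 0.35 per day, 10–40 min)
drop EDA to ~0, cool the temperature toward ambient, and *leave an
elevated plausible HR in place*, so the off-wrist→HR invalidation path is
genuinely exercised. Short artifact bursts (4/h, 5–30 s) inject range and
slope violations.

Incident physiology is an additive boxcar over the 5-minute window from
each red event's recorded onset, plus extra SCR events; the default effect
sizes are the observed incident-minus-reference differences (+9.14 bpm HR,
+0.57 peaks/min, and no SCL or movement shift, since no difference was
found on those measures). The generator writes the exact CSV dialects the
readers consume, and stores ground truth (true onsets and effects, true
off-wrist and artifact spans) separately.

What the generator does *not* emulate — circadian structure beyond a slow
drift, posture, skin-temperature dynamics other than off-wrist cooling,
motion-correlated EDA artifacts, heteroscedastic device noise — bounds what
passing tests show: they validate the pipeline's bookkeeping, masking,
estimator correctness, unbiased effect recovery and type-I calibration
under a plausible signal model, not clinical validity on real children.

## Numerical and design choices

* Timestamps are numeric UTC seconds internally; clock-time features
  (reference matching, dashboard axes) go through the session's IANA zone.
  "Same clock time on another day" is computed calendar-correctly, to the
  second.
* Acceleration counts convert at 1/64 g per count; BVP is carried as
  provenance only — device HR is treated as an opaque input and never
  re-derived from BVP.
* IBI rows with intervals outside (0.2, 3) s are physiologically impossible
  and dropped at parse; a non-monotone IBI file is rejected (with a
  warning) while the rest of the session is kept.
* Reported thresholds and percentages round half *up* (0.0125 → .013), not
  half-to-even; p-values report with 3 decimals below .01 and 2 decimals at
  or above .01, the common manuscript style (0.0657 → .07, 0.0074 → .007).
  Decisions always use exact values.
* A frame needs at least 80% of its window recorded, otherwise it is
  dropped as missing data (configurable); a frame whose window is entirely
  off-wrist yields all-missing summaries — rest-like acceleration from a
  device lying on a table is not movement.
* Degenerate inputs fail loudly where the statistic is undefined
  (zero-variance paired differences, < 2 pairs) but a measure that cannot
  be tested inside the family is reported untestable rather than aborting
  the family.

## Problem sizes used in tests and the acceptance script

The package's stochastic guarantees are exercised on scaled-down study
shapes chosen once: parameter recovery uses the full 30-child, 5-day cohort
with wearing windows shortened to 90 minutes and ~2 red incidents per
child-day (a few hundred pairs); null calibration uses a 4-child, 5-day,
60-minute-window cohort with ~1 red incident per child-day, rerun over 200
seeds in the test suite (100 in the acceptance script). With those sizes
the recovery check resolves the +9 bpm HR effect to a standard error of a
few tenths of a bpm, and the calibration check bounds the per-test type-I
rate near the adjusted level 0.0125.

## Known limitations

* Pairs from the same child are treated as independent, as in the original
  exploratory design; a mixed-effects model is the natural next step and
  deliberately out of scope.
* The artifact rules are heuristics; they are meant to be auditable, not
  optimal. Sensitivity to their thresholds can be explored through the
  configuration, and the split between "artifact" and "off-wrist" depends
  on the 10-minute long-noise threshold.
* SCL comparisons between frames inherit slow tonic drift; the
  clock-time-matched reference design removes the average daily profile
  but not day-specific drift.
* RMSSD from wrist-optical inter-beat intervals in active children is
  sparse by nature; the package surfaces it for display and refuses to
  push it into inference.
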
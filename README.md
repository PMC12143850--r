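# e4arousal

Incident-aligned psychophysiology from wrist-worn biosensor recordings in
children with disruptive behavior.

Clinical teams increasingly put research-grade wristbands (EDA, skin
temperature, triaxial acceleration, blood volume pulse, device-derived HR,
inter-beat intervals) on children in psychiatric care to understand arousal
around aggressive incidents. The raw exports are messy — motion artifacts,
long off-wrist stretches during which the device still reports a
plausible-looking heart rate, sparse inter-beat data — and behavior arrives
as a separate traffic-light observation log (green = good, orange =
disruptive, red = physical aggression) at minute resolution. This package
turns those two inputs into quality-masked signals, derived arousal
measures, and a within-person incident-vs-reference inference.

## The analysis at its core

For every red incident at recorded onset $t_0$, a 5-minute frame
$[t_0, t_0 + 300\,\mathrm{s})$ is summarized on four measures: mean movement
(g), mean HR (bpm), mean tonic skin conductance level SCL (µS), and SCR
peaks per minute (PPM). Reference frames are taken from the **same child at
the same local clock time on the other wearing days**; references
overlapping any aggression observation are excluded, and any frame with
more than 75% EDA artifacts is excluded (a frame at exactly 75% is kept).
Each usable incident then contributes one pair $(x_i^{\text{inc}},
\bar{x}_i^{\text{ref}})$, and for each measure the paired *t* statistic

$$t = \frac{\bar d}{s_d / \sqrt{n}}, \qquad d_i = x_i^{\text{inc}} - \bar x_i^{\text{ref}},$$

is evaluated two-sided against the Bonferroni-adjusted level
$\alpha = 0.05/4 = 0.0125$ (reported as .013).

Upstream, EDA is screened in 5-s epochs by transparent rules (conductance
outside 0.05–60 µS, slope above 10 µS/s, skin temperature below 30 °C);
artifact runs of ≥ 10 min become *off-wrist*, and off-wrist spans blank the
device HR, which is otherwise artificially high while the watch is off the
wrist. SCL is a 30-s moving average of raw EDA over valid samples; SCR
peaks are trough-to-peak events on the phasic component (raw − SCL) with
amplitude ≥ 0.05 µS; movement is the rectified moving-median-subtracted
acceleration norm; RMSSD heart-rate variability is computed from chained
inter-beat intervals but kept out of inference (valid IBI coverage is
sparse in active children).

Because the underlying clinical recordings are not distributable, a seeded
synthetic-cohort generator reproduces the study's input dialect end to end
(30 children, 5 days, clinic/daycare wearing windows, incident rates, and
incident-locked arousal effects), with ground truth stored separately.

## Worked example

Simulate a study-shaped cohort (30 children, 5 days, ~2 red incidents per
child-day, 90-minute wearing windows to keep the example fast) with the
default injected effects (+9.14 bpm HR and +0.57 peaks/min during red
incidents, nothing on SCL or movement), then run the whole pipeline:

```r
library(e4arousal)

cfg <- synthConfig(
  wearing   = list(clinic = c(8, 9.5), daycare = c(8, 9.5)),
  incidents = list(red_per_day = 2, orange_per_day = 1),
  include_bvp = FALSE)
cohort    <- generateCohort(cfg, seed = 1)
processed <- processCohort(cohort$sessions)
analysis  <- runFrameAnalysis(processed, cohort$observations)

analysis$results[, c("measure", "n_pairs", "mean_incident", "mean_reference",
                     "mean_diff", "t", "df", "p_reported", "significant")]
#>      measure n_pairs mean_incident mean_reference mean_diff       t  df p_reported significant
#> 1 movement_g     212       0.05041        0.04862  0.001787  0.4137 211       0.68       FALSE
#> 2     hr_bpm     212     104.40267       95.03726  9.365411 33.8751 211       0.00        TRUE
#> 3     scl_uS     212       4.89373        4.82411  0.069614  1.4957 211       0.14       FALSE
#> 4        ppm     212       3.05264        2.56049  0.492156  8.8035 211       0.00        TRUE
```

The pipeline recovers the injected effects where they exist (HR: estimated
+9.37 bpm against +9.14 injected; PPM: +0.49 against +0.57) and stays null
where nothing was injected — at 212 pairs this synthetic run has far more
power than a 33-pair clinical sample, so the PPM trend reaches
significance here. The exclusion bookkeeping is conserved and reported:

```r
analysis$exclusions
#> $n_candidate_references    964
#> $n_aggression_overlap      192   (19.9% of candidates)
#> $n_frames_artifact_checked 1013
#> $n_artifact_excluded        98   ( 9.7%)
#> $n_retained                915
```

Per-day dashboards and summaries:

```r
wd   <- generateWorkedDay("peter_day3", seed = 2)
proc <- processSession(wd$session)
renderDay(proc, wd$events)          # five stacked panels, marks on SCL
hrDistributionReport(list(proc), age = 12)
collectionSummary(cohort$sessions)
```

All thresholds (epoch length, artifact rules, long-noise threshold, SCL
window, SCR parameters, frame length, 75% artifact threshold, overlap
colors) live in `pipelineConfig()` / YAML via `readPipelineConfig()`.

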
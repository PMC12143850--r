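Package: e4arousal
Title: Incident-Aligned Psychophysiology from Wrist-Worn Biosensor Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis pipeline for multi-channel wrist-worn
    biosensor recordings (Empatica E4 raw export layout) paired with
    traffic-light behavioral observation logs, as used to study
    psychophysiological arousal around aggressive incidents in children.
    Reads and writes per-channel CSV sessions (EDA, skin temperature,
    acceleration, blood volume pulse, heart rate, inter-beat intervals);
    classifies electrodermal-activity epochs as valid, artifact, or off-wrist
    and propagates off-wrist status to device heart rate; derives movement
    magnitude, tonic skin conductance level, skin-conductance-response peaks
    per minute, and RMSSD heart-rate variability; extracts 5-minute incident
    frames with within-person, same-clock-time reference frames on other
    wearing days; applies artifact and aggression-overlap exclusion rules; and
    runs Bonferroni-corrected paired t tests across the four arousal measures.
    A seeded synthetic-cohort generator emulates the full input dialect
    (tonic drift, phasic responses, motion artifacts, off-wrist dropouts,
    incident-locked arousal effects) for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    patchwork,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
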
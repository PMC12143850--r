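#' Default pipeline configuration
#'
#' All tunable thresholds of the pipeline in one nested list, overridable via
#' \code{...} (partial nested lists are merged) or a YAML file
#' (\code{\link{readPipelineConfig}}).
#'
#' Quality: 5 s epochs; EDA validity floor 0.05 uS and ceiling 60 uS; maximum
#' physiological slope 10 uS/s; skin-contact temperature floor 30 C;
#' long-noise (off-wrist) threshold 600 s. Features: 30 s SCL window; SCR
#' minimum amplitude 0.05 uS, minimum rise 0.25 s, minimum separation 1 s;
#' RMSSD minimum 10 successive pairs; 60 s movement median;
#' peaks-per-minute denominator \code{"valid"} (artifact time does not
#' deflate the rate; set \code{"wall"} for plain wall minutes). Frames:
#' 300 s windows; artifact-fraction exclusion threshold 0.75 (strictly
#' greater excludes); aggression-overlap colors red+orange (conservative;
#' set \code{"red"} for red-only); 300 s incident merge window; minimum 0.8
#' of a window recorded; 60 s event-timestamp uncertainty half-width.
#'
#' @param ... named overrides, e.g. \code{quality = list(epoch_s = 10)}
#' @return nested configuration list
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    quality = list(epoch_s = 5, eda_floor_uS = 0.05, eda_ceiling_uS = 60,
                   max_slope_uS_per_s = 10, temp_floor_C = 30,
                   long_noise_s = 600),
    features = list(scl_window_s = 30, scr_min_amp_uS = 0.05,
                    scr_min_rise_s = 0.25, scr_min_separation_s = 1,
                    rmssd_min_beats = 10, movement_median_s = 60,
                    ppm_denominator = "valid"),
    frames = list(frame_s = 300, artifact_threshold = 0.75,
                  overlap_colors = c("red", "orange"), merge_window_s = 300,
                  min_coverage = 0.8, event_uncertainty_s = 60),
    stats = list(family_alpha = 0.05)
  )
  deep_merge(cfg, list(...))
}

deep_merge <- function(base, override) {
  # positional iteration: later duplicates of a name win
  for (i in seq_along(override)) {
    nm <- names(override)[i]
    if (is.null(nm) || !nzchar(nm)) next
    if (is.list(override[[i]]) && is.list(base[[nm]]))
      base[[nm]] <- deep_merge(base[[nm]], override[[i]])
    else base[[nm]] <- override[[i]]
  }
  base
}

#' Read a YAML pipeline configuration
#'
#' Keys mirror \code{\link{pipelineConfig}} (e.g. \code{quality.epoch_s},
#' \code{features.scl_window_s}, \code{frames.artifact_threshold}); missing
#' keys keep their defaults.
#'
#' @param path YAML file
#' @return nested configuration list
#' @export
readPipelineConfig <- function(path) {
  deep_merge(pipelineConfig(), yaml::read_yaml(path))
}

#' Run quality and feature derivation for one session
#'
#' Classifies EDA epochs, detects off-wrist spans, blanks device HR in them,
#' and derives the SCL series, SCR peaks and movement magnitude — everything
#' the frame analysis needs from one session.
#'
#' @param session an \code{e4_session}
#' @param config from \code{\link{pipelineConfig}}
#' @param keep_raw keep the raw channels on the result (default FALSE to
#'   bound memory on large cohorts; EDA/HR/TEMP are always retained)
#' @return an \code{e4_processed} list: session metadata, \code{mask},
#'   invalidated \code{hr}, \code{scl}, \code{peaks}, \code{movement},
#'   \code{ibi}, \code{span}
#' @export
processSession <- function(session, config = pipelineConfig(),
                           keep_raw = FALSE) {
  q <- config$quality; f <- config$features
  eda <- session$channels$EDA
  mask <- classifyEdaEpochs(eda, session$channels$TEMP,
                            epoch_s = q$epoch_s, eda_floor = q$eda_floor_uS,
                            eda_ceiling = q$eda_ceiling_uS,
                            max_slope = q$max_slope_uS_per_s,
                            temp_floor = q$temp_floor_C)
  mask <- detectOffWrist(mask, long_noise_s = q$long_noise_s)
  hr <- invalidateHrOffWrist(session$channels$HR, mask)
  scl <- smoothEda(eda, mask, window_s = f$scl_window_s)
  peaks <- detectScrPeaks(eda, mask, min_amplitude = f$scr_min_amp_uS,
                          min_rise = f$scr_min_rise_s,
                          min_separation = f$scr_min_separation_s,
                          scl_window_s = f$scl_window_s)
  movement <- movementMagnitude(session$channels$ACC_X, session$channels$ACC_Y,
                                session$channels$ACC_Z,
                                median_s = f$movement_median_s)
  structure(list(
    participant_id = session$participant_id, setting = session$setting,
    day_index = session$day_index, timezone = session$timezone,
    span = sessionSpan(session), mask = mask, hr = hr, scl = scl,
    peaks = peaks, movement = movement, ibi = session$ibi,
    temp = session$channels$TEMP,
    session = if (keep_raw) session else NULL
  ), class = "e4_processed")
}

#' Process every session of a cohort
#' @param sessions list of \code{e4_session}
#' @param config from \code{\link{pipelineConfig}}
#' @param keep_raw see \code{\link{processSession}}
#' @return list of \code{e4_processed}
#' @export
processCohort <- function(sessions, config = pipelineConfig(),
                          keep_raw = FALSE) {
  lapply(sessions, processSession, config = config, keep_raw = keep_raw)
}

#' Full incident analysis on processed sessions
#'
#' The end-to-end inference path: extract 5-minute incident frames at red
#' onsets, build same-clock-time reference frames on the other wearing days,
#' apply aggression-overlap and artifact exclusions, assemble per-measure
#' paired tables, and run the Bonferroni-corrected paired t family.
#'
#' @param processed list of \code{e4_processed} (see
#'   \code{\link{processCohort}})
#' @param log an \code{observation_log}
#' @param config from \code{\link{pipelineConfig}}
#' @return list: \code{frames} (the frame ledger), \code{pairs} (per-measure
#'   paired tables), \code{results} (\code{\link{runFamily}} output),
#'   \code{exclusions} (\code{\link{exclusionSummary}} output)
#' @export
runFrameAnalysis <- function(processed, log, config = pipelineConfig()) {
  inc <- extractIncidentFrames(log, processed, config)
  refs <- buildReferenceFrames(inc, processed, log, config)
  ledger <- dplyr::bind_rows(inc, refs)
  ledger <- filterArtifactFrames(ledger, config$frames$artifact_threshold)
  pairs <- assemblePairs(ledger)
  results <- runFamily(pairs, family_alpha = config$stats$family_alpha)
  list(frames = ledger, pairs = pairs, results = results,
       exclusions = exclusionSummary(ledger))
}
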
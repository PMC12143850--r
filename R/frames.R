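FRAME_MEASURES <- c("movement_g", "hr_bpm", "scl_uS", "ppm")

frame_row <- function(frame_id, incident_id, participant_id, kind, day_index,
                      start, end, summaries = NULL, status = "retained",
                      reason = NA_character_) {
  s <- summaries %||% list(artifact_fraction = NA_real_, movement_g = NA_real_,
                           hr_bpm = NA_real_, scl_uS = NA_real_,
                           ppm = NA_real_)
  tibble::tibble(
    frame_id = frame_id, incident_id = incident_id,
    participant_id = participant_id, kind = kind,
    day_index = as.integer(day_index), start = start, end = end,
    artifact_fraction = s$artifact_fraction,
    movement_g = s$movement_g, hr_bpm = s$hr_bpm, scl_uS = s$scl_uS,
    ppm = s$ppm, status = status, exclusion_reason = reason
  )
}

#' Summarize one 5-minute window from processed signals
#'
#' Per-measure means over valid samples inside \code{[start, end)}: movement
#' magnitude, device HR (off-wrist samples already missing), SCL over samples
#' in valid epochs, and peaks per minute with the configured denominator.
#' Each measure is independently missing when its source holds no valid
#' sample in the window. The artifact fraction is the time-weighted share of
#' EDA epochs labeled artifact or off-wrist.
#'
#' @param proc an \code{e4_processed}
#' @param start,end window bounds, numeric UTC seconds
#' @param config from \code{\link{pipelineConfig}}
#' @return list: artifact_fraction, movement_g, hr_bpm, scl_uS, ppm
#' @export
summarizeFrame <- function(proc, start, end, config = pipelineConfig()) {
  af <- maskArtifactFraction(proc$mask, start, end)

  # a fully off-wrist window measures nothing: every summary is missing
  # (rest-like acceleration from a device on a table is not movement)
  ov <- interval_overlap(proc$mask$start, proc$mask$end, start, end)
  off_frac <- if (sum(ov) > 0)
    sum(ov[proc$mask$label == "off_wrist"]) / sum(ov) else NA_real_
  if (isTRUE(off_frac >= 1 - 1e-9))
    return(list(artifact_fraction = af, movement_g = NA_real_,
                hr_bpm = NA_real_, scl_uS = NA_real_, ppm = NA_real_))

  masked_mean <- function(times, values, valid = NULL) {
    inw <- times >= start & times < end
    v <- values[inw]
    if (!is.null(valid)) v <- v[valid[inw]]
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else mean(v)
  }
  mov <- masked_mean(proc$movement$time, proc$movement$value)
  hr <- masked_mean(channelTimes(proc$hr), proc$hr$values)
  scl_lab <- mask_label_at(proc$mask, proc$scl$time)
  scl <- masked_mean(proc$scl$time, proc$scl$value,
                     valid = !is.na(scl_lab) & scl_lab == "valid")
  vf <- if (identical(config$features$ppm_denominator, "wall")) 1 else
    if (is.na(af)) NA_real_ else 1 - af
  ppm <- if (is.na(vf)) NA_real_ else
    peaksPerMinute(proc$peaks, start, end, valid_fraction = vf)
  list(artifact_fraction = af, movement_g = mov, hr_bpm = hr, scl_uS = scl,
       ppm = ppm)
}

# sessions of one participant, as index tibble
proc_index <- function(processed) {
  tibble::tibble(
    i = seq_along(processed),
    participant_id = vapply(processed, `[[`, character(1), "participant_id"),
    day_index = vapply(processed, `[[`, integer(1), "day_index"),
    start = vapply(processed, function(p) p$span[1], numeric(1)),
    end = vapply(processed, function(p) p$span[2], numeric(1))
  )
}

#' Extract incident frames at red-incident onsets
#'
#' One 5-minute frame per red observation with wearable coverage: the
#' recorded incident time is the frame start. Red events starting within one
#' merge window of an already-anchored incident are folded into that frame
#' (a single escalation is not double-counted). Events without sufficient
#' overlapping recording produce an excluded row with reason
#' \code{missing_data}.
#'
#' @param log an \code{observation_log}
#' @param processed list of \code{e4_processed}
#' @param config from \code{\link{pipelineConfig}}
#' @return incident-frame ledger (tibble; see \code{\link{summarizeFrame}}
#'   for the summary columns)
#' @export
extractIncidentFrames <- function(log, processed, config = pipelineConfig()) {
  fcfg <- config$frames
  idx <- proc_index(processed)
  red <- log[log$color == "red", , drop = FALSE]
  rows <- list()
  n_id <- 0L
  for (pid in unique(red$participant_id)) {
    ev <- sort(red$time[red$participant_id == pid])
    anchors <- numeric(0)
    for (t in ev)
      if (!length(anchors) || t - anchors[length(anchors)] >= fcfg$merge_window_s)
        anchors <- c(anchors, t)
    cand <- idx[idx$participant_id == pid, , drop = FALSE]
    for (t in anchors) {
      n_id <- n_id + 1L
      fid <- sprintf("%s_inc%03d", pid, n_id)
      wend <- t + fcfg$frame_s
      if (nrow(cand)) {
        ov <- interval_overlap(cand$start, cand$end, t, wend)
        best <- which.max(ov)
      } else ov <- 0
      if (!nrow(cand) || max(ov) / fcfg$frame_s < fcfg$min_coverage) {
        rows[[length(rows) + 1L]] <- frame_row(
          fid, fid, pid, "incident", NA, t, wend,
          status = "excluded", reason = "missing_data")
        next
      }
      proc <- processed[[cand$i[best]]]
      s <- summarizeFrame(proc, t, wend, config)
      rows[[length(rows) + 1L]] <- frame_row(
        fid, fid, pid, "incident", proc$day_index, t, wend, summaries = s)
    }
  }
  if (!length(rows)) return(frame_row(character(0), character(0), character(0),
                                      character(0), integer(0), numeric(0),
                                      numeric(0))[0, ])
  dplyr::bind_rows(rows)
}

#' Build same-clock-time reference frames for incidents
#'
#' For every retained incident frame, candidate references are the windows at
#' the same local clock time on the participant's other wearing days with
#' recording. A candidate is excluded with reason \code{aggression_overlap}
#' when any aggression observation (colors per
#' \code{config$frames$overlap_colors}, widened by the event-timestamp
#' uncertainty) overlaps its window, and with \code{missing_data} when less
#' than the minimum coverage of the window was recorded. Retained candidates
#' are summarized like incidents; the artifact-fraction filter is applied
#' afterwards to incidents and references alike.
#'
#' @param incident_frames ledger from \code{\link{extractIncidentFrames}}
#' @param processed list of \code{e4_processed}
#' @param log the \code{observation_log}
#' @param config from \code{\link{pipelineConfig}}
#' @return reference-frame ledger (tibble), linked to incidents by
#'   \code{incident_id}
#' @export
buildReferenceFrames <- function(incident_frames, processed, log,
                                 config = pipelineConfig()) {
  fcfg <- config$frames
  u <- attr(log, "uncertainty_s") %||% fcfg$event_uncertainty_s
  idx <- proc_index(processed)
  rows <- list()
  inc <- incident_frames[incident_frames$status == "retained", , drop = FALSE]
  for (r in seq_len(nrow(inc))) {
    pid <- inc$participant_id[r]
    t0 <- inc$start[r]
    others <- idx[idx$participant_id == pid & idx$day_index != inc$day_index[r], ,
                  drop = FALSE]
    if (!nrow(others)) next
    k <- 0L
    for (j in seq_len(nrow(others))) {
      proc <- processed[[others$i[j]]]
      tz <- proc$timezone
      sod <- local_seconds_of_day(t0, tz)
      rstart <- time_at_local(local_date(proc$span[1], tz), sod, tz)
      rend <- rstart + fcfg$frame_s
      k <- k + 1L
      fid <- sprintf("%s_ref%d", inc$incident_id[r], k)
      cov <- interval_overlap(proc$span[1], proc$span[2], rstart, rend) /
        fcfg$frame_s
      if (cov < fcfg$min_coverage) {
        rows[[length(rows) + 1L]] <- frame_row(
          fid, inc$incident_id[r], pid, "reference", proc$day_index,
          rstart, rend, status = "excluded", reason = "missing_data")
        next
      }
      ev <- log[log$participant_id == pid & log$color %in% fcfg$overlap_colors, ,
                drop = FALSE]
      # the uncertainty interval is closed: an event recorded one half-width
      # from the window edge still collides
      overlaps <- nrow(ev) > 0 &&
        any(ev$time + u >= rstart & ev$time - u < rend)
      if (overlaps) {
        rows[[length(rows) + 1L]] <- frame_row(
          fid, inc$incident_id[r], pid, "reference", proc$day_index,
          rstart, rend, status = "excluded", reason = "aggression_overlap")
        next
      }
      s <- summarizeFrame(proc, rstart, rend, config)
      rows[[length(rows) + 1L]] <- frame_row(
        fid, inc$incident_id[r], pid, "reference", proc$day_index,
        rstart, rend, summaries = s)
    }
  }
  if (!length(rows)) return(incident_frames[0, ])
  dplyr::bind_rows(rows)
}

#' Exclude frames exceeding the artifact-fraction threshold
#'
#' Frames whose EDA artifact fraction is strictly greater than the threshold
#' are deemed unreliable and excluded with reason \code{artifact_gt_75}
#' ("more than 75% artifacts"); a frame at exactly the threshold is retained.
#' Applies to incident and reference frames alike; frames whose artifact
#' fraction could not be computed are excluded as \code{missing_data}.
#'
#' @param frames a frame ledger
#' @param threshold artifact-fraction threshold (default 0.75)
#' @return the ledger with statuses updated
#' @export
filterArtifactFrames <- function(frames, threshold = 0.75) {
  live <- frames$status == "retained"
  over <- live & !is.na(frames$artifact_fraction) &
    frames$artifact_fraction > threshold
  frames$status[over] <- "excluded"
  frames$exclusion_reason[over] <- "artifact_gt_75"
  nocov <- live & is.na(frames$artifact_fraction)
  frames$status[nocov] <- "excluded"
  frames$exclusion_reason[nocov] <- "missing_data"
  frames
}

#' Assemble per-measure paired tables
#'
#' One row per incident with at least one retained reference: the incident's
#' value and the mean over its retained references, per measure. A row is
#' dropped for a measure (only for that measure) when either side is missing.
#'
#' @param frames a frame ledger after \code{\link{filterArtifactFrames}}
#' @return named list over \code{movement_g}, \code{hr_bpm}, \code{scl_uS},
#'   \code{ppm} of tibbles with columns \code{incident_id},
#'   \code{participant_id}, \code{incident}, \code{reference}, \code{n_refs}
#' @export
assemblePairs <- function(frames) {
  inc <- frames[frames$kind == "incident" & frames$status == "retained", ,
                drop = FALSE]
  ref <- frames[frames$kind == "reference" & frames$status == "retained", ,
                drop = FALSE]
  out <- list()
  for (m in FRAME_MEASURES) {
    rows <- lapply(seq_len(nrow(inc)), function(r) {
      iv <- inc[[m]][r]
      rr <- ref[ref$incident_id == inc$incident_id[r], m, drop = TRUE]
      rr <- rr[is.finite(rr)]
      if (!is.finite(iv) || !length(rr)) return(NULL)
      tibble::tibble(incident_id = inc$incident_id[r],
                     participant_id = inc$participant_id[r],
                     incident = iv, reference = mean(rr),
                     n_refs = length(rr))
    })
    out[[m]] <- dplyr::bind_rows(rows)
  }
  out
}

#' Exclusion accounting for a frame ledger
#'
#' Conservation and the two headline exclusion rates: candidate reference
#' frames excluded for aggression overlap (as a percent of all candidate
#' references, 1 decimal), and frames excluded for exceeding the artifact
#' threshold (as a percent of frames that reached artifact filtering,
#' 1 decimal).
#'
#' @param frames a frame ledger after \code{\link{filterArtifactFrames}}
#' @return list of counts and percentages
#' @export
exclusionSummary <- function(frames) {
  refs <- frames[frames$kind == "reference", , drop = FALSE]
  n_candidates <- nrow(refs)
  n_overlap <- sum(refs$exclusion_reason %in% "aggression_overlap")
  reached <- frames$status == "retained" |
    frames$exclusion_reason %in% "artifact_gt_75"
  n_frames <- sum(reached)
  n_artifact <- sum(frames$exclusion_reason %in% "artifact_gt_75")
  list(
    n_candidate_references = n_candidates,
    n_aggression_overlap = n_overlap,
    aggression_overlap_pct = if (n_candidates)
      roundHalfUp(100 * n_overlap / n_candidates, 1) else NA_real_,
    n_frames_artifact_checked = n_frames,
    n_artifact_excluded = n_artifact,
    artifact_excluded_pct = if (n_frames)
      roundHalfUp(100 * n_artifact / n_frames, 1) else NA_real_,
    n_missing_data = sum(frames$exclusion_reason %in% "missing_data"),
    n_retained = sum(frames$status == "retained")
  )
}

#' Export the frame ledger as CSV
#' @param frames a frame ledger
#' @param path output CSV
#' @export
writeFrameLedger <- function(frames, path) {
  out <- as.data.frame(frames)
  out$start <- format(as_posix(out$start), "%Y-%m-%dT%H:%M:%SZ")
  out$end <- format(as_posix(out$end), "%Y-%m-%dT%H:%M:%SZ")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
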
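#' Epoch-level EDA quality classification
#'
#' Labels fixed-length epochs of the 4 Hz EDA channel as \code{valid} or
#' \code{artifact} with rule-based heuristics in the spirit of wearable-EDA
#' screening tools: an epoch is an artifact when (i) any sample lies below the
#' conductance floor or above the ceiling, (ii) the absolute sample-to-sample
#' slope exceeds the maximum physiological rate of change, or (iii) skin
#' temperature drops below the skin-contact floor. Rules that fired are kept
#' as provenance per epoch. Off-wrist relabeling is a second pass
#' (\code{\link{detectOffWrist}}).
#'
#' @param eda EDA \code{e4_channel} (4 Hz)
#' @param temp skin-temperature channel, or NULL to skip the temperature rule
#'   (skipped with a warning)
#' @param epoch_s epoch length in seconds (default 5)
#' @param eda_floor,eda_ceiling conductance validity range in microsiemens
#'   (defaults 0.05 and 60)
#' @param max_slope maximum physiological |dEDA/dt| in microsiemens per second
#'   (default 10)
#' @param temp_floor minimum skin-contact temperature in degrees Celsius
#'   (default 30)
#' @return a \code{quality_mask}: tibble with columns \code{start}, \code{end}
#'   (numeric UTC seconds), \code{label} and \code{rules_fired}, plus
#'   attributes \code{channel} and \code{epoch_s}
#' @export
classifyEdaEpochs <- function(eda, temp = NULL, epoch_s = 5,
                              eda_floor = 0.05, eda_ceiling = 60,
                              max_slope = 10, temp_floor = 30) {
  stopifnot(inherits(eda, "e4_channel"))
  n <- length(eda$values)
  if (n == 0L) {
    m <- tibble::tibble(start = numeric(0), end = numeric(0),
                        label = character(0), rules_fired = character(0))
    return(as_quality_mask(m, epoch_s))
  }
  v <- eda$values
  per_epoch <- epoch_s * eda$rate
  epoch_idx <- floor((seq_len(n) - 1) / per_epoch) + 1
  n_epochs <- max(epoch_idx)

  range_bad <- !is.finite(v) | v < eda_floor | v > eda_ceiling
  slope_bad <- rep(FALSE, n)
  if (n > 1L) {
    sl <- abs(diff(v)) * eda$rate
    sl[!is.finite(sl)] <- 0  # non-finite samples already caught by range rule
    # attribute an excess slope to the later of the two samples
    slope_bad[-1] <- sl > max_slope
  }
  fired_range <- as.vector(rowsum(as.numeric(range_bad), epoch_idx) > 0)
  fired_slope <- as.vector(rowsum(as.numeric(slope_bad), epoch_idx) > 0)

  fired_temp <- rep(FALSE, n_epochs)
  if (is.null(temp)) {
    warnf("temperature channel missing: skin-contact rule skipped")
  } else if (length(temp$values)) {
    tt <- channelTimes(temp)
    te <- floor((tt - eda$start_time) / epoch_s) + 1
    ok <- te >= 1 & te <= n_epochs & is.finite(temp$values)
    if (any(ok)) {
      low <- rowsum(as.numeric(temp$values[ok] < temp_floor), te[ok]) > 0
      fired_temp[as.integer(rownames(low))] <- as.vector(low)
    }
  }

  lab <- ifelse(fired_range | fired_slope | fired_temp, "artifact", "valid")
  rules <- vapply(seq_len(n_epochs), function(i) {
    paste(c("range", "slope", "temp")[c(fired_range[i], fired_slope[i],
                                        fired_temp[i])], collapse = ",")
  }, character(1))

  starts <- eda$start_time + (seq_len(n_epochs) - 1) * epoch_s
  ends <- pmin(starts + epoch_s, eda$start_time + n / eda$rate)
  m <- tibble::tibble(start = starts, end = ends, label = lab,
                      rules_fired = rules)
  as_quality_mask(m, epoch_s)
}

#' Construct a quality mask from epoch labels
#'
#' Builds the epoch table \code{\link{classifyEdaEpochs}} produces directly
#' from a label vector — useful for retention bookkeeping on known label
#' sequences and for testing downstream stages in isolation.
#'
#' @param labels character vector over consecutive epochs, each one of
#'   \code{"valid"}, \code{"artifact"}, \code{"off_wrist"}
#' @param start_time first epoch start, numeric UTC seconds
#' @param epoch_s epoch length in seconds
#' @return a \code{quality_mask}
#' @export
qualityMask <- function(labels, start_time = 0, epoch_s = 5) {
  stopifnot(all(labels %in% c("valid", "artifact", "off_wrist")))
  n <- length(labels)
  starts <- start_time + (seq_len(n) - 1) * epoch_s
  as_quality_mask(tibble::tibble(
    start = starts, end = starts + epoch_s, label = labels,
    rules_fired = ifelse(labels == "valid", "", "range")), epoch_s)
}

as_quality_mask <- function(m, epoch_s, channel = "EDA") {
  attr(m, "epoch_s") <- epoch_s
  attr(m, "channel") <- channel
  class(m) <- c("quality_mask", class(m))
  m
}

#' Relabel long artifact runs as off-wrist
#'
#' Maximal runs of consecutive artifact epochs whose total duration reaches
#' the long-noise threshold are relabeled \code{off_wrist}: prolonged absence
#' of valid signal means the watch was probably not on the wrist. Shorter runs
#' stay \code{artifact}; \code{valid} epochs are never touched, and the
#' operation is idempotent.
#'
#' @param mask a \code{quality_mask} from \code{\link{classifyEdaEpochs}}
#' @param long_noise_s threshold in seconds (default 600, i.e. 10 minutes)
#' @return the relabeled \code{quality_mask}
#' @export
detectOffWrist <- function(mask, long_noise_s = 600) {
  if (nrow(mask) == 0L) return(mask)
  bad <- mask$label %in% c("artifact", "off_wrist")
  r <- rle(bad)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i <- idx_start[k]:idx_end[k]
    dur <- sum(mask$end[i] - mask$start[i])
    if (dur >= long_noise_s) mask$label[i] <- "off_wrist"
  }
  mask
}

#' Off-wrist spans of a mask
#' @param mask a \code{quality_mask}
#' @return tibble with \code{start}, \code{end} of each maximal off-wrist run
#' @export
offWristSpans <- function(mask) {
  off <- mask$label == "off_wrist"
  if (!any(off)) return(tibble::tibble(start = numeric(0), end = numeric(0)))
  r <- rle(off)
  ie <- cumsum(r$lengths); is <- ie - r$lengths + 1
  keep <- which(r$values)
  tibble::tibble(start = mask$start[is[keep]], end = mask$end[ie[keep]])
}

#' Blank device HR during off-wrist spans
#'
#' The device keeps emitting a (typically artificially high) heart rate even
#' when it is not worn, so HR samples whose timestamps fall inside off-wrist
#' spans of the EDA mask are replaced by missing values. All other samples are
#' unchanged.
#'
#' @param hr HR \code{e4_channel} (1 Hz)
#' @param mask a \code{quality_mask} that has been through
#'   \code{\link{detectOffWrist}}
#' @return the HR channel with off-wrist samples set to \code{NA}
#' @export
invalidateHrOffWrist <- function(hr, mask) {
  spans <- offWristSpans(mask)
  if (nrow(spans) == 0L || length(hr$values) == 0L) return(hr)
  tt <- channelTimes(hr)
  drop <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(spans)))
    drop <- drop | (tt >= spans$start[i] & tt < spans$end[i])
  hr$values[drop] <- NA_real_
  hr
}

mask_durations <- function(mask) {
  d <- mask$end - mask$start
  c(raw = sum(d),
    off_wrist = sum(d[mask$label == "off_wrist"]),
    artifact = sum(d[mask$label == "artifact"]))
}

#' Data-retention accounting from raw to artifact-free hours
#'
#' Per participant (and averaged over participants): raw recorded EDA hours,
#' hours after removing long noise (off-wrist spans), and hours after also
#' removing artifacts, with the percent reduction at each stage relative to
#' the preceding stage, rounded to integer percent. Average-row percentages
#' are computed from the averaged hours, matching how such retention tables
#' are reported.
#'
#' @param masks list of \code{quality_mask}, one per session
#' @param participant_ids character vector parallel to \code{masks}; sessions
#'   of the same participant are pooled
#' @return list with tibbles \code{by_participant} and \code{average}
#' @export
retentionReport <- function(masks, participant_ids) {
  stopifnot(length(masks) == length(participant_ids))
  per <- lapply(masks, mask_durations)
  d <- tibble::tibble(
    participant_id = as.character(participant_ids),
    raw = vapply(per, `[[`, numeric(1), "raw"),
    off = vapply(per, `[[`, numeric(1), "off_wrist"),
    art = vapply(per, `[[`, numeric(1), "artifact")
  )
  agg <- stats::aggregate(cbind(raw, off, art) ~ participant_id, d, sum)
  mk <- function(raw_s, off_s, art_s) {
    raw_h <- raw_s / 3600
    noise_free_h <- (raw_s - off_s) / 3600
    clean_h <- (raw_s - off_s - art_s) / 3600
    red1 <- ifelse(raw_h > 0, roundHalfUp(100 * (raw_h - noise_free_h) / raw_h), 0)
    red2 <- ifelse(noise_free_h > 0,
                   roundHalfUp(100 * (noise_free_h - clean_h) / noise_free_h), 0)
    tibble::tibble(raw_hours = raw_h, hours_after_long_noise = noise_free_h,
                   reduction_long_noise_pct = red1,
                   hours_after_artifacts = clean_h,
                   reduction_artifact_pct = red2)
  }
  by_p <- dplyr::bind_cols(tibble::tibble(participant_id = agg$participant_id),
                           mk(agg$raw, agg$off, agg$art))
  avg <- mk(mean(agg$raw), mean(agg$off), mean(agg$art))
  list(by_participant = by_p, average = avg)
}

#' Export a quality mask as CSV
#' @param mask a \code{quality_mask}
#' @param path output file
#' @export
writeQualityMask <- function(mask, path) {
  out <- data.frame(
    epoch_start_utc = format(as_posix(mask$start), "%Y-%m-%dT%H:%M:%OS2Z"),
    epoch_end_utc = format(as_posix(mask$end), "%Y-%m-%dT%H:%M:%OS2Z"),
    label = mask$label, rules_fired = mask$rules_fired
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# per-sample labels of a mask at given times ("valid" outside mask coverage
# is never assumed: times outside coverage get NA)
mask_label_at <- function(mask, times) {
  if (nrow(mask) == 0L) return(rep(NA_character_, length(times)))
  epoch_s <- attr(mask, "epoch_s")
  idx <- floor((times - mask$start[1]) / epoch_s) + 1
  lab <- rep(NA_character_, length(times))
  ok <- idx >= 1 & idx <= nrow(mask)
  # guard against times in the open gap beyond a short final epoch
  ok[ok] <- times[ok] < mask$end[idx[ok]]
  lab[ok] <- mask$label[idx[ok]]
  lab
}

# time-weighted fraction of [start,end) labeled artifact/off_wrist,
# relative to the mask-covered part of the window
maskArtifactFraction <- function(mask, start, end) {
  if (nrow(mask) == 0L) return(NA_real_)
  ov <- interval_overlap(mask$start, mask$end, start, end)
  covered <- sum(ov)
  if (covered <= 0) return(NA_real_)
  bad <- mask$label %in% c("artifact", "off_wrist")
  sum(ov[bad]) / covered
}
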
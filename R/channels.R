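CHANNEL_NAMES <- c("EDA", "TEMP", "ACC_X", "ACC_Y", "ACC_Z", "BVP", "HR")

#' Single biosensor channel
#'
#' A uniformly sampled signal from one sensor of the wrist device: a start
#' time on the absolute (UTC) clock, a sampling rate, and the ordered sample
#' values in channel units (EDA in microsiemens, TEMP in degrees Celsius,
#' acceleration in g, HR in beats per minute, BVP in arbitrary units).
#' Missing samples are explicit \code{NA}s, never zeros: a zero EDA reading is
#' physiologically meaningful (off-wrist signature).
#'
#' @param name one of \code{"EDA"}, \code{"TEMP"}, \code{"ACC_X"},
#'   \code{"ACC_Y"}, \code{"ACC_Z"}, \code{"BVP"}, \code{"HR"}
#' @param start_time session start as numeric UTC seconds (fractional allowed)
#' @param rate sampling rate in Hz, positive
#' @param values numeric sample vector
#' @return an object of class \code{e4_channel}
#' @export
e4Channel <- function(name, start_time, rate, values) {
  name <- match.arg(name, CHANNEL_NAMES)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stopf("channel %s: rate must be a single positive number", name)
  if (!is.numeric(start_time) || length(start_time) != 1L || !is.finite(start_time))
    stopf("channel %s: start_time must be a single finite number", name)
  structure(
    list(name = name, start_time = as.numeric(start_time),
         rate = as.numeric(rate), values = as.numeric(values)),
    class = "e4_channel"
  )
}

#' @export
print.e4_channel <- function(x, ...) {
  cat(sprintf("<e4_channel %s> %d samples @ %g Hz (%.1f s) starting %s UTC\n",
              x$name, length(x$values), x$rate, channelDuration(x),
              format(as_posix(x$start_time))))
  invisible(x)
}

#' Sample timestamps of a channel
#' @param channel an \code{e4_channel}
#' @return numeric UTC seconds, one per sample
#' @export
channelTimes <- function(channel) {
  if (length(channel$values) == 0L) return(numeric(0))
  channel$start_time + (seq_along(channel$values) - 1) / channel$rate
}

#' Duration of a channel in seconds (samples / rate)
#' @param channel an \code{e4_channel}
#' @export
channelDuration <- function(channel) length(channel$values) / channel$rate

#' Inter-beat interval series
#'
#' Irregular series of detected heartbeats: offsets in seconds from the
#' session start, each paired with the interval (seconds) since the previous
#' detected beat. Physiologically impossible intervals (outside
#' \code{(0.2, 3)} s) are discarded at construction; the device only emits a
#' row when two consecutive pulse peaks were reliably detected, so the series
#' is often sparse or empty.
#'
#' @param start_time numeric UTC seconds
#' @param offsets seconds from \code{start_time}, strictly increasing
#' @param intervals beat-to-beat intervals in seconds
#' @return an object of class \code{ibi_series}
#' @export
ibiSeries <- function(start_time, offsets = numeric(0), intervals = numeric(0)) {
  stopifnot(length(offsets) == length(intervals))
  keep <- is.finite(offsets) & is.finite(intervals) &
    intervals > 0.2 & intervals < 3.0
  offsets <- offsets[keep]; intervals <- intervals[keep]
  if (length(offsets) > 1L && any(diff(offsets) <= 0))
    stopf("ibi series: offsets must be strictly increasing")
  structure(
    list(start_time = as.numeric(start_time),
         offsets = as.numeric(offsets), intervals = as.numeric(intervals)),
    class = "ibi_series"
  )
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d beats starting %s UTC\n",
              length(x$offsets), format(as_posix(x$start_time))))
  invisible(x)
}

#' One wearable session (one participant, one wearing day)
#'
#' Bundles the per-sensor channels of a single recording with participant
#' metadata. Channels keep their native rates and start times; all channels
#' must overlap on the wall clock. BVP is optional in memory (the pipeline
#' treats device HR as opaque and never re-derives it from BVP), but is always
#' present in sessions read from a raw export.
#'
#' @param participant_id opaque pseudonymous code (never a device serial)
#' @param channels named list of \code{e4_channel}; must include EDA, TEMP,
#'   ACC_X/Y/Z, HR
#' @param ibi an \code{ibi_series} (possibly empty)
#' @param setting \code{"clinic"} or \code{"daycare"}
#' @param day_index wearing day, 1..5
#' @param timezone IANA zone used to map the UTC clock to local clock time
#' @return an object of class \code{e4_session}
#' @export
e4Session <- function(participant_id, channels, ibi = NULL,
                      setting = c("clinic", "daycare"), day_index = 1L,
                      timezone = "UTC") {
  setting <- match.arg(setting)
  nm <- vapply(channels, function(ch) ch$name, character(1))
  names(channels) <- nm
  if (anyDuplicated(nm))
    stopf("session: duplicate channel %s", nm[duplicated(nm)][1])
  required <- setdiff(CHANNEL_NAMES, "BVP")
  missing <- setdiff(required, nm)
  if (length(missing))
    stopf("session: missing channel(s) %s", paste(missing, collapse = ", "))
  nonempty <- Filter(function(ch) length(ch$values) > 0, channels)
  if (length(nonempty) > 1L) {
    s <- max(vapply(nonempty, function(ch) ch$start_time, numeric(1)))
    e <- min(vapply(nonempty, function(ch) ch$start_time + channelDuration(ch),
                    numeric(1)))
    if (e <= s) stopf("session: channels do not overlap in wall-clock time")
  }
  if (is.null(ibi)) {
    ibi <- ibiSeries(channels[["EDA"]]$start_time)
  }
  structure(
    list(participant_id = as.character(participant_id), setting = setting,
         day_index = as.integer(day_index), timezone = timezone,
         channels = channels, ibi = ibi),
    class = "e4_session"
  )
}

#' @export
print.e4_session <- function(x, ...) {
  cat(sprintf("<e4_session> participant %s, %s day %d (%s)\n",
              x$participant_id, x$setting, x$day_index, x$timezone))
  for (ch in x$channels)
    cat(sprintf("  %-5s %8d samples @ %2g Hz\n", ch$name,
                length(ch$values), ch$rate))
  cat(sprintf("  IBI   %8d beats\n", length(x$ibi$offsets)))
  invisible(x)
}

#' Extract a channel from a session
#' @param session an \code{e4_session}
#' @param name channel name
#' @return the \code{e4_channel}, or NULL if absent (BVP only)
#' @export
sessionChannel <- function(session, name) session$channels[[name]]

#' Recording span of a session
#'
#' Start and end (numeric UTC seconds) of the EDA channel, which anchors all
#' quality and frame bookkeeping.
#' @param session an \code{e4_session}
#' @return numeric length-2 vector \code{c(start, end)}
#' @export
sessionSpan <- function(session) {
  eda <- session$channels[["EDA"]]
  c(eda$start_time, eda$start_time + channelDuration(eda))
}
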
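OBS_COLORS <- c("green", "orange", "red")

#' Behavioral observation log (traffic-light model)
#'
#' Timestamped behavior codes recorded by staff, teachers and research
#' observers: \code{green} = good behavior, \code{orange} = disruptive
#' behavior (swearing, not listening, challenging, being agitated, ...),
#' \code{red} = physical aggression and severe disruptive behavior (kicking,
#' hitting, threatening, destroying things, ...). Timestamps carry minute
#' resolution (observers wrote clock times); an uncertainty half-width
#' (default one minute) is used only for overlap tests against analysis
#' windows.
#'
#' @param events tibble with columns \code{participant_id}, \code{time}
#'   (numeric UTC seconds), \code{color}, \code{description}, \code{observer}
#' @param timezone IANA zone the clock times were recorded in
#' @param uncertainty_s timestamp uncertainty half-width, seconds
#' @return an \code{observation_log}
#' @export
observationLog <- function(events, timezone = "UTC", uncertainty_s = 60) {
  stopifnot(all(c("participant_id", "time", "color", "description",
                  "observer") %in% names(events)))
  bad <- !events$color %in% OBS_COLORS
  if (any(bad))
    stopf("unknown color value(s): %s", paste(unique(events$color[bad]),
                                              collapse = ", "))
  events <- events[order(events$participant_id, events$time), , drop = FALSE]
  dup <- duplicated(events)
  if (any(dup))
    warnf("%d exact-duplicate observation row(s) kept (two observer streams may double-report; use dedupObservations() to drop)",
          sum(dup))
  out <- tibble::as_tibble(events)
  attr(out, "timezone") <- timezone
  attr(out, "uncertainty_s") <- uncertainty_s
  class(out) <- c("observation_log", class(out))
  out
}

#' Read an observation CSV
#'
#' Columns: \code{participant_id}, \code{local_datetime}
#' (\code{YYYY-mm-dd HH:MM} in the given zone), \code{color}
#' (green/orange/red), \code{description}, \code{observer}. Rows with unknown
#' colors or unparseable datetimes are rejected row-wise with their line
#' numbers reported in a warning; the remaining rows form the log. An empty
#' file yields an empty log.
#'
#' @param path CSV file
#' @param timezone IANA zone of the recorded clock times
#' @return an \code{observation_log}
#' @export
readObservations <- function(path, timezone = "UTC") {
  raw <- utils::read.csv(path, colClasses = "character")
  empty <- tibble::tibble(participant_id = character(0), time = numeric(0),
                          color = character(0), description = character(0),
                          observer = character(0))
  if (nrow(raw) == 0L) return(observationLog(empty, timezone))
  tm <- as.POSIXct(strptime(raw$local_datetime, "%Y-%m-%d %H:%M:%S",
                            tz = timezone))
  alt <- as.POSIXct(strptime(raw$local_datetime, "%Y-%m-%d %H:%M",
                             tz = timezone))
  tm[is.na(tm)] <- alt[is.na(tm)]
  bad_time <- is.na(tm)
  bad_color <- !raw$color %in% OBS_COLORS
  bad <- bad_time | bad_color
  if (any(bad)) {
    # +1 for the header line
    warnf("rejected %d observation row(s) at line(s) %s (%s)",
          sum(bad), paste(which(bad) + 1L, collapse = ", "),
          paste(c(if (any(bad_time)) "unparseable datetime",
                  if (any(bad_color)) "unknown color"), collapse = "; "))
  }
  keep <- !bad
  ev <- tibble::tibble(
    participant_id = raw$participant_id[keep],
    time = as.numeric(tm[keep]),
    color = raw$color[keep],
    description = raw$description[keep],
    observer = raw$observer[keep]
  )
  observationLog(ev, timezone)
}

#' Write an observation log as CSV (round-trips with readObservations)
#' @param log an \code{observation_log}
#' @param path output CSV
#' @export
writeObservations <- function(log, path) {
  tz <- attr(log, "timezone") %||% "UTC"
  out <- data.frame(
    participant_id = log$participant_id,
    local_datetime = format(as_posix(log$time, tz), "%Y-%m-%d %H:%M:%S"),
    color = log$color,
    description = log$description,
    observer = log$observer
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Drop exact-duplicate observation rows
#' @param log an \code{observation_log}
#' @return the deduplicated log
#' @export
dedupObservations <- function(log) {
  log[!duplicated(tibble::as_tibble(log)), , drop = FALSE]
}

#' Export observation tallies as JSON
#' @param log an \code{observation_log}
#' @param path output JSON file
#' @export
writeTallies <- function(log, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stopf("jsonlite is required for JSON export")
  tl <- tallyObservations(log)
  jsonlite::write_json(list(by_color = tl$by_color,
                            aggression_total = tl$aggression_total),
                       path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' Tally observations by color
#'
#' Counts per color and distinct participants per color. Green marks good
#' behavior and is excluded from the aggression total (red + orange).
#'
#' @param log an \code{observation_log}
#' @return list with tibble \code{by_color} (\code{color}, \code{n},
#'   \code{n_participants}) and scalar \code{aggression_total}
#' @export
tallyObservations <- function(log) {
  by_color <- tibble::tibble(
    color = OBS_COLORS,
    n = vapply(OBS_COLORS, function(cl) sum(log$color == cl), numeric(1),
               USE.NAMES = FALSE),
    n_participants = vapply(OBS_COLORS, function(cl)
      length(unique(log$participant_id[log$color == cl])), numeric(1),
      USE.NAMES = FALSE)
  )
  list(by_color = by_color,
       aggression_total = sum(log$color %in% c("red", "orange")))
}
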
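# Raw-export dialect: one directory (or zip) per session with EDA.csv,
# TEMP.csv, ACC.csv (3 columns), BVP.csv, HR.csv; row 1 = Unix start time,
# row 2 = sampling rate, remaining rows = samples. IBI.csv (optional):
# row 1 = start time, remaining rows = "offset,interval".

read_channel_csv <- function(file, name, expect_cols = 1L) {
  m <- tryCatch(
    as.matrix(utils::read.csv(file, header = FALSE, colClasses = "numeric")),
    error = function(e) stopf("cannot parse %s: %s", basename(file), conditionMessage(e))
  )
  if (nrow(m) < 2L)
    stopf("%s: expected start-time and rate header rows", basename(file))
  if (ncol(m) != expect_cols)
    stopf("%s: expected %d column(s), found %d", basename(file), expect_cols, ncol(m))
  start <- m[1, 1]
  rate <- m[2, 1]
  vals <- if (nrow(m) > 2L) m[-(1:2), , drop = FALSE] else
    matrix(numeric(0), ncol = expect_cols)
  list(start = start, rate = rate, values = vals)
}

#' Read a raw wearable session directory or zip
#'
#' Parses the per-channel CSV export of one session into an
#' \code{\link{e4Session}}. Acceleration counts are converted to g
#' (1/64 g per count). IBI rows with non-physiological intervals are dropped
#' at parse; a non-monotone IBI file is rejected with a warning while the rest
#' of the session is kept.
#'
#' @param path session directory, or a \code{.zip} containing the CSVs
#' @param timezone IANA zone for clock-time features
#' @param participant_id,setting,day_index session metadata (not part of the
#'   raw export; defaults are placeholders)
#' @return an \code{e4_session}
#' @export
readE4Session <- function(path, timezone = "UTC", participant_id = "P00",
                          setting = "clinic", day_index = 1L) {
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("e4session")
    unzip(path, exdir = exdir)
    # tolerate a single top-level folder inside the zip
    inner <- list.dirs(exdir, recursive = FALSE)
    path <- if (!file.exists(file.path(exdir, "EDA.csv")) && length(inner) == 1L)
      inner else exdir
    on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  }
  need <- c("EDA.csv", "TEMP.csv", "ACC.csv", "BVP.csv", "HR.csv")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stopf("session at %s: required file %s is missing", path, f)

  eda <- read_channel_csv(file.path(path, "EDA.csv"), "EDA")
  temp <- read_channel_csv(file.path(path, "TEMP.csv"), "TEMP")
  acc <- read_channel_csv(file.path(path, "ACC.csv"), "ACC", expect_cols = 3L)
  bvp <- read_channel_csv(file.path(path, "BVP.csv"), "BVP")
  hr <- read_channel_csv(file.path(path, "HR.csv"), "HR")

  channels <- list(
    e4Channel("EDA", eda$start, eda$rate, eda$values[, 1]),
    e4Channel("TEMP", temp$start, temp$rate, temp$values[, 1]),
    e4Channel("ACC_X", acc$start, acc$rate, acc$values[, 1] / 64),
    e4Channel("ACC_Y", acc$start, acc$rate, acc$values[, 2] / 64),
    e4Channel("ACC_Z", acc$start, acc$rate, acc$values[, 3] / 64),
    e4Channel("BVP", bvp$start, bvp$rate, bvp$values[, 1]),
    e4Channel("HR", hr$start, hr$rate, hr$values[, 1])
  )

  ibi_file <- file.path(path, "IBI.csv")
  ibi <- NULL
  if (file.exists(ibi_file)) {
    lines <- readLines(ibi_file, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) >= 1L) {
      ibi_start <- suppressWarnings(as.numeric(strsplit(lines[1], ",")[[1]][1]))
      if (length(lines) > 1L) {
        body <- do.call(rbind, lapply(strsplit(lines[-1], ","), function(p)
          suppressWarnings(as.numeric(p[1:2]))))
        off <- body[, 1]; iv <- body[, 2]
        keep <- is.finite(off) & is.finite(iv)
        off <- off[keep]; iv <- iv[keep]
        phys <- iv > 0.2 & iv < 3.0
        off <- off[phys]; iv <- iv[phys]
        if (length(off) > 1L && any(diff(off) <= 0)) {
          warnf("IBI.csv: offsets not strictly increasing; IBI series rejected")
          ibi <- ibiSeries(ibi_start)
        } else {
          ibi <- ibiSeries(ibi_start, off, iv)
        }
      } else {
        ibi <- ibiSeries(ibi_start)
      }
    }
  }

  e4Session(participant_id, channels, ibi = ibi, setting = setting,
            day_index = day_index, timezone = timezone)
}

#' Write a session in the raw-export CSV dialect
#'
#' Emits the exact layout \code{\link{readE4Session}} accepts, so that the
#' synthetic generator and the reader speak the same dialect and
#' read-after-write is the identity up to float formatting. Acceleration is
#' written back in 1/64-g counts.
#'
#' @param session an \code{e4_session}
#' @param path directory to create/fill
#' @return \code{path}, invisibly
#' @export
writeE4Session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(file, start, rate, mat) {
    con <- file.path(path, file)
    hdr <- rbind(rep(start, ncol(mat)), rep(rate, ncol(mat)))
    utils::write.table(format(rbind(hdr, mat), digits = 15, trim = TRUE,
                              scientific = FALSE),
                       con, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  ch <- session$channels
  wr("EDA.csv", ch$EDA$start_time, ch$EDA$rate, cbind(ch$EDA$values))
  wr("TEMP.csv", ch$TEMP$start_time, ch$TEMP$rate, cbind(ch$TEMP$values))
  wr("ACC.csv", ch$ACC_X$start_time, ch$ACC_X$rate,
     cbind(ch$ACC_X$values, ch$ACC_Y$values, ch$ACC_Z$values) * 64)
  bvp <- ch$BVP
  if (is.null(bvp)) bvp <- e4Channel("BVP", ch$EDA$start_time, 64, numeric(0))
  wr("BVP.csv", bvp$start_time, bvp$rate, cbind(bvp$values))
  wr("HR.csv", ch$HR$start_time, ch$HR$rate, cbind(ch$HR$values))
  ibi_lines <- c(format(session$ibi$start_time, digits = 15, scientific = FALSE))
  if (length(session$ibi$offsets))
    ibi_lines <- c(ibi_lines, paste(
      format(session$ibi$offsets, digits = 15, trim = TRUE, scientific = FALSE),
      format(session$ibi$intervals, digits = 15, trim = TRUE, scientific = FALSE),
      sep = ","))
  writeLines(ibi_lines, file.path(path, "IBI.csv"))
  invisible(path)
}

#' Resample all channels of a session onto one clock grid
#'
#' Downsamples every channel to a shared grid by averaging the raw samples
#' falling in each grid bin (mean-within-bin); bins containing no samples are
#' \code{NA}. The grid starts at the earliest channel start and covers the
#' union of channel spans. Used by the dashboard so all measures share one
#' time axis.
#'
#' @param session an \code{e4_session}
#' @param grid_rate target rate in Hz; must not exceed the rate of any
#'   non-empty channel unless \code{allow_sparse} is set
#' @param allow_sparse place channels slower than the grid into their bins
#'   anyway (bins without samples are NA) instead of refusing to upsample
#' @return a tibble with column \code{time} (bin start, numeric UTC seconds)
#'   and one column per channel
#' @export
clockAlign <- function(session, grid_rate = 4, allow_sparse = FALSE) {
  chans <- Filter(function(ch) length(ch$values) > 0, session$channels)
  if (!length(chans)) stopf("clockAlign: session has no samples")
  starts <- vapply(chans, function(ch) ch$start_time, numeric(1))
  ends <- vapply(chans, function(ch) ch$start_time + channelDuration(ch), numeric(1))
  if (min(ends) <= max(starts) && length(chans) > 1L)
    stopf("clockAlign: channels have zero wall-clock overlap")
  if (!allow_sparse)
    for (ch in chans)
      if (grid_rate > ch$rate)
        stopf("clockAlign: grid rate %g Hz exceeds %s rate %g Hz (set allow_sparse = TRUE to keep NA gaps)",
              grid_rate, ch$name, ch$rate)
  t0 <- min(starts); t1 <- max(ends)
  n_bins <- ceiling((t1 - t0) * grid_rate - 1e-9)
  grid <- t0 + (seq_len(n_bins) - 1) / grid_rate
  out <- tibble::tibble(time = grid)
  for (ch in session$channels) {
    if (is.null(ch) || length(ch$values) == 0L) next
    idx <- floor((channelTimes(ch) - t0) * grid_rate) + 1
    ok <- idx >= 1 & idx <= n_bins & is.finite(ch$values)
    sums <- counts <- numeric(n_bins)
    if (any(ok)) {
      tab <- tapply(ch$values[ok], idx[ok], sum)
      pos <- as.integer(names(tab))
      sums[pos] <- tab
      cnt <- tapply(rep(1, sum(ok)), idx[ok], sum)
      counts[pos] <- cnt
    }
    v <- sums / counts
    v[counts == 0] <- NA_real_
    out[[ch$name]] <- v
  }
  out
}
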
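#' Derived measurement series
#'
#' Thin tibble wrapper for a derived measure on a time grid: columns
#' \code{time} (numeric UTC seconds) and \code{value}, with attributes
#' \code{measure} and \code{window_s}.
#'
#' @param time numeric UTC seconds
#' @param value numeric values with NA for missing
#' @param measure one of movement_g, scl_uS, ppm, hr_bpm, hrv_rmssd_ms, temp_C
#' @param window_s smoothing/aggregation window used, seconds
#' @return a \code{derived_series} tibble
#' @export
derivedSeries <- function(time, value, measure, window_s = NA_real_) {
  measure <- match.arg(measure, c("movement_g", "scl_uS", "ppm", "hr_bpm",
                                  "hrv_rmssd_ms", "temp_C"))
  out <- tibble::tibble(time = time, value = value)
  attr(out, "measure") <- measure
  attr(out, "window_s") <- window_s
  class(out) <- c("derived_series", class(out))
  out
}

# centered running sum via cumsum; x must contain no NA
running_sum <- function(x, before, after) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - before, 1)
  hi <- pmin(seq_len(n) + after, n)
  cs[hi + 1] - cs[lo]
}

#' Movement magnitude from triaxial acceleration
#'
#' Per-sample Euclidean norm of acceleration with the static (gravity)
#' component removed by subtracting a moving median of the norm, rectified,
#' then aggregated onto a coarser analysis grid by mean. At rest the norm is a
#' constant 1 g and movement is ~0; bursts of motion raise the norm away from
#' its local median.
#'
#' @param acc_x,acc_y,acc_z axis channels in g, sharing rate and clock
#' @param median_s moving-median window for the static component, seconds
#'   (default 60)
#' @param grid_s output grid bin, seconds (default 1)
#' @return a \code{derived_series} (measure \code{movement_g})
#' @export
movementMagnitude <- function(acc_x, acc_y, acc_z, median_s = 60, grid_s = 1) {
  if (length(acc_x$values) != length(acc_y$values) ||
      length(acc_x$values) != length(acc_z$values))
    stopf("acceleration axes differ in length")
  if (length(acc_x$values) == 0L)
    return(derivedSeries(numeric(0), numeric(0), "movement_g", median_s))
  norm <- sqrt(acc_x$values^2 + acc_y$values^2 + acc_z$values^2)
  k <- round(median_s * acc_x$rate)
  k <- min(k + (k %% 2 == 0), length(norm) - (length(norm) %% 2 == 0))
  k <- max(k, 1)
  static <- if (length(norm) >= 3 && k >= 3)
    runmed(norm, k, endrule = "constant") else
    rep(stats::median(norm), length(norm))
  mov <- abs(norm - static)
  per_bin <- max(1L, round(grid_s * acc_x$rate))
  n_full <- length(mov) %/% per_bin
  val <- if (n_full > 0)
    .colMeans(mov[seq_len(n_full * per_bin)], per_bin, n_full) else numeric(0)
  if (length(mov) > n_full * per_bin)
    val <- c(val, mean(mov[(n_full * per_bin + 1):length(mov)]))
  t0 <- acc_x$start_time + (seq_along(val) - 1) * per_bin / acc_x$rate
  derivedSeries(t0, val, "movement_g", median_s)
}

# logical per-sample validity of an EDA channel under a mask
eda_sample_valid <- function(eda, mask) {
  ok <- is.finite(eda$values)
  if (!is.null(mask) && nrow(mask) > 0L) {
    lab <- mask_label_at(mask, channelTimes(eda))
    ok <- ok & !is.na(lab) & lab == "valid"
  }
  ok
}

#' Tonic skin conductance level via masked moving average
#'
#' Centered moving average of the raw EDA over valid samples only: samples in
#' artifact or off-wrist epochs (and non-finite samples) do not contribute,
#' and positions whose window holds no valid sample are missing. The smoothed
#' series is the SCL (tonic) series; raw minus SCL is the phasic component
#' used for peak detection.
#'
#' @param eda EDA channel (4 Hz)
#' @param mask a \code{quality_mask}, or NULL to treat all finite samples as
#'   valid
#' @param window_s averaging window in seconds (default 30)
#' @return a \code{derived_series} (measure \code{scl_uS}) on the EDA grid
#' @export
smoothEda <- function(eda, mask = NULL, window_s = 30) {
  n <- length(eda$values)
  if (n == 0L) return(derivedSeries(numeric(0), numeric(0), "scl_uS", window_s))
  w <- max(1L, round(window_s * eda$rate))
  before <- (w - 1) %/% 2
  after <- w - 1 - before
  ok <- eda_sample_valid(eda, mask)
  x <- ifelse(ok, eda$values, 0)
  s <- running_sum(x, before, after)
  cnt <- running_sum(as.numeric(ok), before, after)
  v <- s / cnt
  v[cnt == 0] <- NA_real_
  derivedSeries(channelTimes(eda), v, "scl_uS", window_s)
}

#' Detect skin conductance response peaks
#'
#' Trough-to-peak detection on the phasic component (raw EDA minus the SCL
#' moving average): a local maximum is kept as an SCR when its rise from the
#' preceding trough is at least \code{min_amplitude}, the rise time is at
#' least \code{min_rise}, and it is at least \code{min_separation} after the
#' previously accepted peak. Peaks inside artifact or off-wrist epochs are
#' discarded.
#'
#' @param eda EDA channel (4 Hz)
#' @param mask a \code{quality_mask} or NULL
#' @param min_amplitude minimum trough-to-peak rise, microsiemens
#'   (default 0.05)
#' @param min_rise minimum rise time, seconds (default 0.25)
#' @param min_separation minimum spacing between accepted peaks, seconds
#'   (default 1)
#' @param scl_window_s SCL window used for the phasic decomposition
#' @return tibble with \code{onset_time}, \code{peak_time}, \code{amplitude}
#' @export
detectScrPeaks <- function(eda, mask = NULL, min_amplitude = 0.05,
                           min_rise = 0.25, min_separation = 1,
                           scl_window_s = 30) {
  empty <- tibble::tibble(onset_time = numeric(0), peak_time = numeric(0),
                          amplitude = numeric(0))
  n <- length(eda$values)
  if (n < 3L) return(empty)
  scl <- smoothEda(eda, mask, scl_window_s)
  phasic <- eda$values - scl$value
  ok <- eda_sample_valid(eda, mask) & is.finite(phasic)
  tt <- channelTimes(eda)

  out_on <- out_pk <- out_amp <- numeric(0)
  last_peak_time <- -Inf
  # walk contiguous valid segments
  r <- rle(ok)
  seg_end <- cumsum(r$lengths); seg_start <- seg_end - r$lengths + 1
  for (k in which(r$values)) {
    i0 <- seg_start[k]; i1 <- seg_end[k]
    if (i1 - i0 < 2L) next
    x <- phasic[i0:i1]
    d <- diff(x)
    # collapse plateaus so sign changes are well defined
    s <- sign(d)
    nz <- s != 0
    if (!any(nz)) next
    idx <- which(nz)
    sv <- s[idx]
    turn <- which(diff(sv) != 0)
    # local maxima where slope goes + -> -, minima - -> +
    peaks <- idx[turn][sv[turn] > 0] + 1
    troughs <- idx[turn][sv[turn] < 0] + 1
    troughs <- c(1L, troughs)  # segment start can serve as first trough
    if (!length(peaks)) next
    ti <- findInterval(peaks - 0.5, troughs)
    keep <- ti >= 1
    peaks <- peaks[keep]; tr <- troughs[ti[keep]]
    amp <- x[peaks] - x[tr]
    rise <- (peaks - tr) / eda$rate
    cand <- which(amp >= min_amplitude & rise >= min_rise)
    for (j in cand) {  # separation constraint is inherently sequential
      pk_time <- tt[i0 + peaks[j] - 1]
      if (pk_time - last_peak_time >= min_separation) {
        out_on <- c(out_on, tt[i0 + tr[j] - 1])
        out_pk <- c(out_pk, pk_time)
        out_amp <- c(out_amp, amp[j])
        last_peak_time <- pk_time
      }
    }
  }
  tibble::tibble(onset_time = out_on, peak_time = out_pk, amplitude = out_amp)
}

#' Peaks per minute of valid signal
#'
#' Number of SCR peak times falling in \code{[window_start, window_end)}
#' divided by the valid (non-artifact) minutes of the window. With
#' \code{valid_fraction = 1} this is a plain per-wall-minute rate; passing
#' the window's valid fraction makes artifact time not deflate the rate.
#' Missing when no valid minutes remain.
#'
#' @param peaks tibble from \code{\link{detectScrPeaks}}
#' @param window_start,window_end numeric UTC seconds, end > start
#' @param valid_fraction proportion of the window that is valid signal
#' @return peaks-per-minute value, or NA
#' @export
peaksPerMinute <- function(peaks, window_start, window_end, valid_fraction = 1) {
  if (window_end <= window_start) stopf("window_end must exceed window_start")
  valid_min <- (window_end - window_start) / 60 * valid_fraction
  if (!is.finite(valid_min) || valid_min <= 0) return(NA_real_)
  n <- sum(peaks$peak_time >= window_start & peaks$peak_time < window_end)
  n / valid_min
}

#' RMSSD heart-rate variability from an IBI series
#'
#' Root mean square of successive inter-beat-interval differences over beats
#' inside the window, in milliseconds. A successive difference is only formed
#' between intervals that share a beat the device marked consecutive (the
#' offset gap between adjacent rows equals the later row's interval, within
#' tolerance); differences are never formed across detection gaps. Missing
#' when fewer than \code{min_beats} successive pairs are available — with the
#' sparse IBI coverage typical of active children this is the common case,
#' which is why RMSSD is displayed but kept out of inference.
#'
#' @param ibi an \code{ibi_series}
#' @param window_start,window_end numeric UTC seconds (defaults: whole series)
#' @param min_beats minimum number of successive-difference pairs (default 10)
#' @param gap_tol tolerance in seconds for the consecutiveness check
#'   (default 0.02)
#' @return RMSSD in ms, or NA
#' @export
rmssd <- function(ibi, window_start = -Inf, window_end = Inf,
                  min_beats = 10, gap_tol = 0.02) {
  t_beat <- ibi$start_time + ibi$offsets
  keep <- t_beat >= window_start & t_beat <= window_end
  off <- ibi$offsets[keep]; iv <- ibi$intervals[keep]
  if (length(off) < 2L) return(NA_real_)
  # rows i and i+1 hold successive intervals sharing beat i exactly when the
  # offset gap equals the later row's interval (device marked them chained)
  consec <- abs(diff(off) - iv[-1]) <= gap_tol
  d <- diff(iv)[consec]
  if (length(d) < min_beats) return(NA_real_)
  sqrt(mean(d^2)) * 1000
}

#' Rolling RMSSD series for dashboards
#'
#' RMSSD evaluated on a sliding window, for the HRV panel of the day report.
#'
#' @param ibi an \code{ibi_series}
#' @param t_start,t_end span to cover, numeric UTC seconds
#' @param window_s window length (default 300)
#' @param step_s step between evaluations (default 60)
#' @param min_beats minimum successive pairs per window
#' @return a \code{derived_series} (measure \code{hrv_rmssd_ms}); time is the
#'   window center
#' @export
hrvSeries <- function(ibi, t_start, t_end, window_s = 300, step_s = 60,
                      min_beats = 10) {
  centers <- seq(t_start + window_s / 2, t_end - window_s / 2, by = step_s)
  if (!length(centers))
    return(derivedSeries(numeric(0), numeric(0), "hrv_rmssd_ms", window_s))
  vals <- vapply(centers, function(ct)
    rmssd(ibi, ct - window_s / 2, ct + window_s / 2, min_beats = min_beats),
    numeric(1))
  derivedSeries(centers, vals, "hrv_rmssd_ms", window_s)
}

#' Export derived series as tidy CSV
#' @param series list of \code{derived_series}
#' @param path output file
#' @export
writeDerivedSeries <- function(series, path) {
  rows <- lapply(series, function(s)
    data.frame(timestamp_utc = format(as_posix(s$time), "%Y-%m-%dT%H:%M:%OS2Z"),
               measure = attr(s, "measure"), value = s$value))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
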
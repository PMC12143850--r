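#' Five-panel day dashboard
#'
#' Stacked panels sharing one local-time axis, in the fixed order movement
#' (g), skin temperature (degrees C), SCL (microsiemens), HR (bpm) and HRV
#' (RMSSD, ms). Orange/red observation marks are drawn on the SCL panel,
#' off-wrist spans are shaded, and a 5-minute moving-average overlay plus a
#' day-median reference line are added per panel to aid interpretation. The
#' layout is deterministic given its inputs.
#'
#' @param proc an \code{e4_processed} (see \code{\link{processSession}})
#' @param events an \code{observation_log} (may be empty)
#' @param file optional output path (written via \code{ggplot2::ggsave})
#' @param overlay_window_s moving-average overlay window (default 300)
#' @return a patchwork object of the five panels (invisibly if written)
#' @export
renderDay <- function(proc, events = NULL, file = NULL,
                      overlay_window_s = 300) {
  tz <- proc$timezone
  off <- offWristSpans(proc$mask)

  panel_df <- function(time, value) {
    if (!length(time)) return(data.frame(time = as.POSIXct(character(0)),
                                         value = numeric(0)))
    data.frame(time = as_posix(time, tz), value = value)
  }
  roll <- function(time, value, window_s) {
    if (length(time) < 2L) return(rep(NA_real_, length(time)))
    rate <- 1 / stats::median(diff(time))
    w <- max(1L, round(window_s * rate))
    ok <- is.finite(value)
    s <- running_sum(ifelse(ok, value, 0), (w - 1) %/% 2, w - 1 - (w - 1) %/% 2)
    n <- running_sum(as.numeric(ok), (w - 1) %/% 2, w - 1 - (w - 1) %/% 2)
    out <- s / n
    out[n == 0] <- NA_real_
    out
  }
  mk_panel <- function(time, value, ylab, marks = FALSE) {
    df <- panel_df(time, value)
    df$smooth <- if (nrow(df)) roll(time, value, overlay_window_s) else numeric(0)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = time, y = value))
    if (nrow(off))
      p <- p + ggplot2::annotate("rect",
                                 xmin = as_posix(off$start, tz),
                                 xmax = as_posix(off$end, tz),
                                 ymin = -Inf, ymax = Inf,
                                 alpha = 0.15, fill = "grey40")
    if (nrow(df)) {
      p <- p + ggplot2::geom_line(linewidth = 0.2, colour = "grey55",
                                  na.rm = TRUE) +
        ggplot2::geom_line(ggplot2::aes(y = smooth), colour = "black",
                           linewidth = 0.4, na.rm = TRUE) +
        ggplot2::geom_hline(yintercept = stats::median(value, na.rm = TRUE),
                            linetype = "dashed", linewidth = 0.3,
                            colour = "steelblue")
    }
    if (marks && !is.null(events) && nrow(events)) {
      agg <- events[events$color %in% c("orange", "red"), , drop = FALSE]
      if (nrow(agg))
        p <- p + ggplot2::geom_vline(xintercept = as_posix(agg$time, tz),
                                     colour = ifelse(agg$color == "red",
                                                     "red", "orange"),
                                     linewidth = 0.5)
    }
    p + ggplot2::labs(x = NULL, y = ylab) + ggplot2::theme_minimal(base_size = 9)
  }

  span <- proc$span
  hrv <- hrvSeries(proc$ibi, span[1], span[2])
  p1 <- mk_panel(proc$movement$time, proc$movement$value, "movement (g)")
  p2 <- mk_panel(channelTimes(proc$temp), proc$temp$values, "temp (°C)")
  p3 <- mk_panel(proc$scl$time, proc$scl$value, "SCL (µS)", marks = TRUE)
  p4 <- mk_panel(channelTimes(proc$hr), proc$hr$values, "HR (bpm)")
  p5 <- mk_panel(hrv$time, hrv$value, "HRV RMSSD (ms)")
  fig <- patchwork::wrap_plots(p1, p2, p3, p4, p5, ncol = 1)
  if (!is.null(file)) {
    ggplot2::ggsave(file, fig, width = 10, height = 8, dpi = 120)
    return(invisible(fig))
  }
  fig
}

#' Per-day HR distribution summaries
#'
#' Five-number summary (min, Q1, median, Q3, max; quartiles by linear
#' interpolation, type 7) of valid HR per wearing day, with a flag when the
#' summary leaves the pediatric norm band for the child's age (80-120 bpm
#' ages 6-12, 60-100 bpm ages 12-14). HR must be off-wrist-invalidated first,
#' or spurious off-wrist readings will trip the flag.
#'
#' @param processed list of \code{e4_processed} for one participant
#' @param age child age in years
#' @return tibble: day_index, min, q1, median, q3, max, outside_norm_range
#' @export
hrDistributionReport <- function(processed, age) {
  band <- if (age < 12) c(80, 120) else c(60, 100)
  rows <- lapply(processed, function(p) {
    v <- p$hr$values
    v <- v[is.finite(v)]
    if (!length(v))
      return(tibble::tibble(day_index = p$day_index, min = NA_real_,
                            q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                            max = NA_real_, outside_norm_range = NA))
    q <- unname(quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7))
    tibble::tibble(day_index = p$day_index, min = q[1], q1 = q[2],
                   median = q[3], q3 = q[4], max = q[5],
                   outside_norm_range = q[3] < band[1] | q[3] > band[2] |
                     q[5] > band[2] + 20 | q[1] < band[1] - 20)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$day_index), , drop = FALSE]
}

#' Cohort hours-collected summary
#'
#' Mean recorded hours per child by setting and the percent of the
#' per-setting collection target (60 h at the clinic over 5 days of
#' 08:00-20:00 wearing, 35 h at daycare over 5 days of 08:00-15:00),
#' 1 decimal. Percent-of-target is scale invariant.
#'
#' @param sessions list of \code{e4_session}
#' @param targets named hours targets per setting
#' @return tibble: setting, n_children, mean_hours, target_hours,
#'   pct_of_target
#' @export
collectionSummary <- function(sessions,
                              targets = c(clinic = 60, daycare = 35)) {
  d <- tibble::tibble(
    participant_id = vapply(sessions, `[[`, character(1), "participant_id"),
    setting = vapply(sessions, `[[`, character(1), "setting"),
    hours = vapply(sessions, function(s)
      channelDuration(s$channels$EDA) / 3600, numeric(1))
  )
  per_child <- stats::aggregate(hours ~ participant_id + setting, d, sum)
  rows <- lapply(names(targets), function(st) {
    h <- per_child$hours[per_child$setting == st]
    if (!length(h)) return(NULL)
    tibble::tibble(setting = st, n_children = length(h),
                   mean_hours = mean(h), target_hours = unname(targets[st]),
                   pct_of_target = unname(roundHalfUp(100 * mean(h) / targets[st], 1)))
  })
  dplyr::bind_rows(rows)
}
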
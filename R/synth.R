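#' Synthetic cohort configuration
#'
#' Defaults reproduce the study conditions: 30 children (18 clinic, 12
#' daycare) wearing the device for 5 consecutive weekdays, clinic
#' 08:00-20:00 and daycare 08:00-15:00 local time; HR baselines inside the
#' pediatric norm bands (80-120 bpm ages 6-12, 60-100 bpm ages 12-14); red
#' incidents at 0.36 and orange at 1.74 per child-day (54 and 261 over 150
#' child-days); incident-locked additive effects equal to the observed
#' incident-minus-reference differences (+9.14 bpm HR, +0.57 peaks/min, no
#' SCL or movement shift). Tonic EDA drifts slowly, phasic responses follow a
#' Bateman kernel (0.75 s rise, 3 s decay) at Poisson times, HR is AR(1)
#' around baseline, acceleration mixes rest noise with movement bursts.
#' Off-wrist episodes drop EDA to ~0, cool the temperature toward ambient
#' and leave a plausible-but-wrong elevated device HR in place, so off-wrist
#' handling is genuinely exercised.
#'
#' @param ... named overrides merged into the defaults (nested lists merge
#'   per key), e.g. \code{effects = list(hr_bpm = 0)}
#' @return nested configuration list
#' @export
synthConfig <- function(...) {
  cfg <- list(
    n_participants = 30, n_clinic = 18, days = 5,
    start_date = "2024-03-04", timezone = "Europe/Amsterdam",
    wearing = list(clinic = c(8, 20), daycare = c(8, 15)),
    age_range = c(6, 14),
    hr = list(phi = 0.97, sd = 6),
    scl = list(baseline_range = c(1, 8), drift_amp_uS = 0.8,
               drift_period_h = 3, noise_sd_uS = 0.01),
    scr = list(rate_per_min = 2.6, amp_meanlog = log(0.25), amp_sdlog = 0.5,
               rise_s = 0.75, decay_s = 3),
    temp = list(on_wrist_C = 33, ambient_C = 26, noise_sd_C = 0.05,
                decay_tau_s = 120),
    acc = list(noise_g = 0.02, burst_rate_per_h = 6, burst_dur_s = c(20, 120),
               burst_amp_g = c(0.2, 0.8), burst_freq_hz = 2),
    incidents = list(red_per_day = 0.36, orange_per_day = 1.74),
    effects = list(hr_bpm = 9.14, ppm_per_min = 0.57, scl_uS = 0,
                   movement_g = 0),
    artifacts = list(rate_per_h = 4, dur_s = c(5, 30)),
    off_wrist = list(prob_per_day = 0.35, dur_s = c(600, 2400),
                     hr_elevation_bpm = c(30, 50)),
    ibi = list(coverage = 0.15, segment_s = c(60, 300), jitter_sd_s = 0.03),
    include_bvp = TRUE
  )
  deep_merge(cfg, list(...))
}

runif1 <- function(lim) runif(1, lim[1], lim[2])

# one synthetic participant-day; episodes: list of
# list(onset, dur, hr_bpm, scl_uS, extra_scr, movement_g) absolute-time
# effect windows. Returns list(session, truth list)
build_day <- function(pid, setting, day_index, t0, t1, cfg, person,
                      episodes = list(), off_spans = NULL,
                      artifact_spans = NULL) {
  dur <- t1 - t0
  tz <- cfg$timezone
  n_eda <- round(dur * 4); t_eda <- t0 + (seq_len(n_eda) - 1) / 4
  n_hr <- round(dur * 1); t_hr <- t0 + (seq_len(n_hr) - 1)
  n_acc <- round(dur * 32); t_acc <- t0 + (seq_len(n_acc) - 1) / 32

  # --- off-wrist spans ---
  if (is.null(off_spans)) {
    off_spans <- if (runif(1) < cfg$off_wrist$prob_per_day) {
      d <- runif1(cfg$off_wrist$dur_s)
      s <- runif(1, t0, max(t0, t1 - d))
      cbind(s, min(s + d, t1))
    } else cbind(numeric(0), numeric(0))
  }
  in_spans <- function(tt, spans) {
    out <- rep(FALSE, length(tt))
    for (i in seq_len(nrow(spans)))
      out <- out | (tt >= spans[i, 1] & tt < spans[i, 2])
    out
  }
  off_eda <- in_spans(t_eda, off_spans)

  # --- tonic + phasic EDA ---
  drift_phase <- runif(1, 0, 2 * pi)
  tonic <- person$scl0 +
    cfg$scl$drift_amp_uS * sin(2 * pi * (t_eda - t0) /
                                 (cfg$scl$drift_period_h * 3600) + drift_phase)
  scr_n <- rpois(1, cfg$scr$rate_per_min * dur / 60)
  scr_times <- sort(runif(scr_n, t0, t1))
  for (ep in episodes)
    if ((ep$extra_scr %||% 0) > 0) {
      n_extra <- rpois(1, ep$extra_scr * ep$dur / 60)
      scr_times <- sort(c(scr_times, runif(n_extra, ep$onset, ep$onset + ep$dur)))
    }
  impulse <- numeric(n_eda)
  if (length(scr_times)) {
    amp <- pmax(stats::rlnorm(length(scr_times), cfg$scr$amp_meanlog,
                              cfg$scr$amp_sdlog), 0.05)
    si <- pmin(pmax(floor((scr_times - t0) * 4) + 1, 1), n_eda)
    impulse[si] <- impulse[si] + amp
  }
  kt <- seq(0, 8 * cfg$scr$decay_s, by = 0.25)
  kern <- exp(-kt / cfg$scr$decay_s) - exp(-kt / cfg$scr$rise_s)
  kern <- kern / max(kern)
  phasic <- as.numeric(stats::filter(impulse, kern, method = "convolution",
                                     sides = 1))
  phasic[is.na(phasic)] <- 0
  eda <- tonic + phasic + rnorm(n_eda, 0, cfg$scl$noise_sd_uS)
  for (ep in episodes)
    if ((ep$scl_uS %||% 0) != 0) {
      w <- t_eda >= ep$onset & t_eda < ep$onset + ep$dur
      eda[w] <- eda[w] + ep$scl_uS
    }
  eda <- pmax(eda, 0.06)  # keep clean signal above the validity floor
  eda[off_eda] <- abs(rnorm(sum(off_eda), 0, 0.005))  # off-wrist signature

  # --- artifact bursts ---
  if (is.null(artifact_spans)) {
    n_b <- rpois(1, cfg$artifacts$rate_per_h * dur / 3600)
    if (n_b > 0) {
      bs <- runif(n_b, t0, t1)
      bd <- runif(n_b, cfg$artifacts$dur_s[1], cfg$artifacts$dur_s[2])
      artifact_spans <- cbind(bs, pmin(bs + bd, t1))
    } else artifact_spans <- cbind(numeric(0), numeric(0))
  }
  art_eda <- in_spans(t_eda, artifact_spans) & !off_eda
  eda[art_eda] <- runif(sum(art_eda), 0, 80)

  # --- temperature ---
  temp <- rep(cfg$temp$on_wrist_C, n_eda) + rnorm(n_eda, 0, cfg$temp$noise_sd_C)
  for (i in seq_len(nrow(off_spans))) {
    w <- which(t_eda >= off_spans[i, 1] & t_eda < off_spans[i, 2])
    if (length(w))
      temp[w] <- cfg$temp$ambient_C + (cfg$temp$on_wrist_C - cfg$temp$ambient_C) *
        exp(-(t_eda[w] - off_spans[i, 1]) / cfg$temp$decay_tau_s) +
        rnorm(length(w), 0, cfg$temp$noise_sd_C)
  }

  # --- heart rate: AR(1) around baseline + incident boxcars ---
  phi <- cfg$hr$phi
  innov_sd <- cfg$hr$sd * sqrt(1 - phi^2)
  e <- rnorm(n_hr, 0, innov_sd)
  e[1] <- rnorm(1, 0, cfg$hr$sd)  # stationary start
  ar <- as.numeric(stats::filter(e, phi, method = "recursive"))
  hr <- person$hr0 + ar
  for (ep in episodes)
    if ((ep$hr_bpm %||% 0) != 0) {
      w <- t_hr >= ep$onset & t_hr < ep$onset + ep$dur
      hr[w] <- hr[w] + ep$hr_bpm
    }
  off_hr <- in_spans(t_hr, off_spans)
  if (any(off_hr))  # device keeps reporting: plausible but artificially high
    hr[off_hr] <- person$hr0 + runif1(cfg$off_wrist$hr_elevation_bpm) +
      rnorm(sum(off_hr), 0, 2)

  # --- acceleration: rest + movement bursts ---
  ax <- rnorm(n_acc, 0, cfg$acc$noise_g)
  ay <- rnorm(n_acc, 0, cfg$acc$noise_g)
  az <- 1 + rnorm(n_acc, 0, cfg$acc$noise_g)
  n_mb <- rpois(1, cfg$acc$burst_rate_per_h * dur / 3600)
  if (n_mb > 0) {
    ms <- runif(n_mb, t0, t1)
    md <- runif(n_mb, cfg$acc$burst_dur_s[1], cfg$acc$burst_dur_s[2])
    for (i in seq_len(n_mb)) {
      w <- which(t_acc >= ms[i] & t_acc < ms[i] + md[i])
      if (length(w)) {
        a <- runif1(cfg$acc$burst_amp_g)
        az[w] <- az[w] + a * sin(2 * pi * cfg$acc$burst_freq_hz * (t_acc[w] - ms[i]))
      }
    }
  }
  for (ep in episodes)
    if ((ep$movement_g %||% 0) != 0) {
      w <- which(t_acc >= ep$onset & t_acc < ep$onset + ep$dur)
      az[w] <- az[w] + ep$movement_g * pi / 2 *
        sin(2 * pi * cfg$acc$burst_freq_hz * (t_acc[w] - ep$onset))
    }
  off_acc <- in_spans(t_acc, off_spans)
  if (any(off_acc)) {  # device lying still
    ax[off_acc] <- rnorm(sum(off_acc), 0, 0.002)
    ay[off_acc] <- rnorm(sum(off_acc), 0, 0.002)
    az[off_acc] <- 1 + rnorm(sum(off_acc), 0, 0.002)
  }

  # --- sparse IBI segments (skipping off-wrist time) ---
  ibi_off <- ibi_iv <- numeric(0)
  target <- cfg$ibi$coverage * dur
  covered <- 0
  guard <- 0
  while (covered < target && guard < 50) {
    guard <- guard + 1
    seg_len <- runif1(cfg$ibi$segment_s)
    seg_start <- runif(1, t0, max(t0, t1 - seg_len))
    if (any(in_spans(c(seg_start, seg_start + seg_len), off_spans))) next
    tt <- seg_start
    repeat {
      hr_here <- hr[min(max(floor(tt - t0) + 1, 1), n_hr)]
      iv <- 60 / max(hr_here, 40) + rnorm(1, 0, cfg$ibi$jitter_sd_s)
      iv <- min(max(iv, 0.25), 2.5)
      tt <- tt + iv
      if (tt > seg_start + seg_len) break
      ibi_off <- c(ibi_off, tt - t0)
      ibi_iv <- c(ibi_iv, iv)
    }
    covered <- covered + seg_len
  }
  ord <- order(ibi_off)
  ibi <- ibiSeries(t0, ibi_off[ord], ibi_iv[ord])

  channels <- list(
    e4Channel("EDA", t0, 4, eda),
    e4Channel("TEMP", t0, 4, temp),
    e4Channel("ACC_X", t0, 32, ax),
    e4Channel("ACC_Y", t0, 32, ay),
    e4Channel("ACC_Z", t0, 32, az),
    e4Channel("HR", t0, 1, hr)
  )
  if (isTRUE(cfg$include_bvp)) {
    n_bvp <- round(dur * 64); t_bvp <- (seq_len(n_bvp) - 1) / 64
    bvp <- 30 * sin(2 * pi * (person$hr0 / 60) * t_bvp) + rnorm(n_bvp, 0, 5)
    channels <- c(channels, list(e4Channel("BVP", t0, 64, bvp)))
  }
  session <- e4Session(pid, channels, ibi = ibi, setting = setting,
                       day_index = day_index, timezone = tz)
  list(session = session,
       truth = list(off_wrist = off_spans, artifacts = artifact_spans,
                    scr_times = scr_times))
}

OBS_PHRASES <- list(
  red = c("hitting", "kicking another child", "throwing a chair",
          "pushing and threatening", "destroying materials"),
  orange = c("swearing at staff", "not listening", "challenging the teacher",
             "climbing on furniture", "agitated and arguing"),
  green = c("followed the rules all morning", "helped tidy up",
            "complimented for calm behavior")
)

#' Generate a full synthetic cohort
#'
#' Seeded end-to-end emulation of the study inputs: per participant-day
#' multi-channel sessions, a traffic-light observation log, and a
#' ground-truth ledger (true incident onsets and injected effects, true
#' off-wrist and artifact spans). Red incidents receive the configured
#' additive arousal effects over the 5-minute window from their recorded
#' onset; orange and green observations carry no injected effect. The same
#' seed reproduces the cohort exactly.
#'
#' @param config from \code{\link{synthConfig}}
#' @param seed integer RNG seed
#' @return list: \code{sessions} (named list of \code{e4_session}),
#'   \code{observations} (an \code{observation_log}), \code{truth} (list with
#'   \code{participants}, \code{incidents}, \code{off_wrist},
#'   \code{artifacts})
#' @export
generateCohort <- function(config = synthConfig(), seed = 1) {
  set.seed(seed)
  cfg <- config
  tz <- cfg$timezone
  ids <- sprintf("P%02d", seq_len(cfg$n_participants))
  setting <- ifelse(seq_len(cfg$n_participants) <= cfg$n_clinic,
                    "clinic", "daycare")
  ages <- sample(seq(cfg$age_range[1], cfg$age_range[2]),
                 cfg$n_participants, replace = TRUE)
  hr0 <- ifelse(ages < 12, runif(cfg$n_participants, 90, 110),
                runif(cfg$n_participants, 70, 90))
  scl0 <- runif(cfg$n_participants, cfg$scl$baseline_range[1],
                cfg$scl$baseline_range[2])
  dates <- as.Date(cfg$start_date) + seq_len(cfg$days) - 1

  sessions <- list()
  ev_rows <- list()
  truth_inc <- list()
  truth_off <- list()
  truth_art <- list()
  frame_s <- 300

  for (p in seq_len(cfg$n_participants)) {
    person <- list(age = ages[p], hr0 = hr0[p], scl0 = scl0[p])
    hours <- cfg$wearing[[setting[p]]]
    for (d in seq_len(cfg$days)) {
      t0 <- time_at_local(dates[d], hours[1] * 3600, tz)
      t1 <- time_at_local(dates[d], hours[2] * 3600, tz)
      n_red <- rpois(1, cfg$incidents$red_per_day)
      n_orange <- rpois(1, cfg$incidents$orange_per_day)
      # minute-resolution onsets, kept clear of the session edges
      draw_times <- function(n) {
        if (n == 0) return(numeric(0))
        hi <- max(t0 + 120, t1 - frame_s - 60)
        floor(runif(n, t0 + 60, hi) / 60) * 60
      }
      red_t <- sort(draw_times(n_red))
      orange_t <- sort(draw_times(n_orange))
      episodes <- lapply(red_t, function(tt) list(
        onset = tt, dur = frame_s, hr_bpm = cfg$effects$hr_bpm,
        scl_uS = cfg$effects$scl_uS, extra_scr = cfg$effects$ppm_per_min,
        movement_g = cfg$effects$movement_g))
      day <- build_day(ids[p], setting[p], d, t0, t1, cfg, person, episodes)
      key <- sprintf("%s_day%d", ids[p], d)
      sessions[[key]] <- day$session
      if (length(red_t) || length(orange_t)) {
        cols <- c(rep("red", length(red_t)), rep("orange", length(orange_t)))
        tms <- c(red_t, orange_t)
        ev_rows[[length(ev_rows) + 1L]] <- tibble::tibble(
          participant_id = ids[p], time = tms, color = cols,
          description = vapply(cols, function(cl)
            sample(OBS_PHRASES[[cl]], 1), character(1)),
          observer = sample(c("staff", "researcher", "teacher"),
                            length(tms), replace = TRUE)
        )
      }
      if (length(red_t))
        truth_inc[[length(truth_inc) + 1L]] <- tibble::tibble(
          participant_id = ids[p], day_index = d, onset = red_t,
          hr_bpm = cfg$effects$hr_bpm, ppm_per_min = cfg$effects$ppm_per_min,
          scl_uS = cfg$effects$scl_uS, movement_g = cfg$effects$movement_g)
      if (nrow(day$truth$off_wrist))
        truth_off[[length(truth_off) + 1L]] <- tibble::tibble(
          session = key, start = day$truth$off_wrist[, 1],
          end = day$truth$off_wrist[, 2])
      if (nrow(day$truth$artifacts))
        truth_art[[length(truth_art) + 1L]] <- tibble::tibble(
          session = key, start = day$truth$artifacts[, 1],
          end = day$truth$artifacts[, 2])
    }
  }
  events <- if (length(ev_rows)) dplyr::bind_rows(ev_rows) else
    tibble::tibble(participant_id = character(0), time = numeric(0),
                   color = character(0), description = character(0),
                   observer = character(0))
  log <- observationLog(events, timezone = tz)
  list(
    sessions = sessions,
    observations = log,
    truth = list(
      participants = tibble::tibble(participant_id = ids, setting = setting,
                                    age = ages, hr_baseline = hr0,
                                    scl_baseline = scl0),
      incidents = dplyr::bind_rows(truth_inc),
      off_wrist = dplyr::bind_rows(truth_off),
      artifacts = dplyr::bind_rows(truth_art)
    )
  )
}

#' Write a synthetic cohort to disk in the raw-export dialect
#'
#' One directory per session (named \code{<participant>_day<d>}), one
#' observation CSV, and the ground truth as JSON — exactly the dialects the
#' reader functions consume.
#'
#' @param cohort from \code{\link{generateCohort}}
#' @param dir output directory
#' @return \code{dir}, invisibly
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(cohort$sessions))
    writeE4Session(cohort$sessions[[key]], file.path(dir, key))
  writeObservations(cohort$observations, file.path(dir, "observations.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Scripted single-day sessions for dashboard documentation
#'
#' Two deterministic (seeded) template days for smoke tests and the day
#' report. \code{"frank_day1"}: a clinic day with five orange incidents, some
#' co-timed with an SCL response and at least one without any, plus an
#' unexplained multi-measure peak in the evening. \code{"peter_day3"}: a
#' clinic day with SCL peaks around a morning therapy session, a small SCL
#' peak at an orange incident around 15:00, and an exercise bout where
#' movement and SCL rise together.
#'
#' @param template \code{"frank_day1"} or \code{"peter_day3"}
#' @param seed RNG seed
#' @return list with \code{session}, \code{events} (an
#'   \code{observation_log}) and \code{truth}
#' @export
generateWorkedDay <- function(template = c("frank_day1", "peter_day3"),
                              seed = 1) {
  template <- match.arg(template)
  set.seed(seed)
  cfg <- synthConfig(off_wrist = list(prob_per_day = 0),
                     artifacts = list(rate_per_h = 1))
  tz <- cfg$timezone
  date <- as.Date(cfg$start_date) + if (template == "peter_day3") 2 else 0
  t0 <- time_at_local(date, 8 * 3600, tz)
  t1 <- time_at_local(date, 20 * 3600, tz)
  at <- function(h, m = 0) time_at_local(date, h * 3600 + m * 60, tz)
  person <- list(age = if (template == "peter_day3") 12 else 10,
                 hr0 = if (template == "peter_day3") 82 else 98,
                 scl0 = 3)
  if (template == "frank_day1") {
    ev <- tibble::tibble(
      participant_id = "FRANK", color = "orange",
      time = c(at(9, 15), at(9, 50), at(12, 0), at(14, 30), at(16, 45)),
      description = c("removed from class", "removed from class again",
                      "agitated walking clinic to school",
                      "arguing with staff", "challenging, not listening"),
      observer = c("teacher", "teacher", "staff", "staff", "staff"))
    episodes <- list(
      # two school incidents without any physiological response
      list(onset = at(12, 0), dur = 300, hr_bpm = 8, scl_uS = 0.3,
           extra_scr = 2, movement_g = 0.25),
      list(onset = at(14, 30), dur = 300, scl_uS = 0.8, extra_scr = 4),
      list(onset = at(16, 45), dur = 300, scl_uS = 0.5, extra_scr = 3),
      # unexplained evening peak across measures, no observation
      list(onset = at(18, 30), dur = 420, hr_bpm = 12, scl_uS = 1.5,
           extra_scr = 5, movement_g = 0.15))
  } else {
    ev <- tibble::tibble(
      participant_id = "PETER", color = "orange",
      time = at(15, 0),
      description = "upset about change in daily routine",
      observer = "staff")
    episodes <- list(
      # EMDR therapy session: sustained SCL elevation, no movement
      list(onset = at(10, 30), dur = 2700, hr_bpm = 6, scl_uS = 1.2,
           extra_scr = 3),
      # orange incident with a minor SCL peak
      list(onset = at(15, 0), dur = 300, scl_uS = 0.4, extra_scr = 2),
      # physical exercise: SCL and movement rise together
      list(onset = at(16, 30), dur = 1800, hr_bpm = 25, scl_uS = 2,
           extra_scr = 4, movement_g = 0.5))
  }
  pid <- ev$participant_id[1]
  day <- build_day(pid, "clinic", if (template == "peter_day3") 3L else 1L,
                   t0, t1, cfg, person, episodes)
  list(session = day$session,
       events = observationLog(ev[, c("participant_id", "time", "color",
                                      "description", "observer")],
                               timezone = tz),
       truth = c(day$truth, list(episodes = episodes)))
}
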
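# In-code fixture builders shared across the test files.

T0 <- as.numeric(as.POSIXct("2024-03-04 08:00:00", tz = "UTC"))

# constant-valued channel
const_channel <- function(name, value, duration_s, rate, start = T0) {
  e4Channel(name, start, rate, rep(value, round(duration_s * rate)))
}

# a minimal clean session: constant EDA/TEMP/HR, resting ACC
make_session <- function(duration_s = 600, eda = 2, temp = 33, hr = 95,
                         start = T0, pid = "P01", day = 1L, tz = "UTC",
                         with_bvp = TRUE, ibi = NULL) {
  channels <- list(
    const_channel("EDA", eda, duration_s, 4, start),
    const_channel("TEMP", temp, duration_s, 4, start),
    const_channel("ACC_X", 0, duration_s, 32, start),
    const_channel("ACC_Y", 0, duration_s, 32, start),
    const_channel("ACC_Z", 1, duration_s, 32, start)
  )
  if (with_bvp)
    channels <- c(channels, list(const_channel("BVP", 0, duration_s, 64, start)))
  channels <- c(channels, list(const_channel("HR", hr, duration_s, 1, start)))
  e4Session(pid, channels, ibi = ibi, setting = "clinic", day_index = day,
            timezone = tz)
}

# quality mask built directly from a label vector (5 s epochs)
make_mask <- function(labels, epoch_s = 5, start = T0) {
  qualityMask(labels, start_time = start, epoch_s = epoch_s)
}

# observation log from vectors
make_log <- function(participant_id, time, color,
                     description = "x", observer = "staff", tz = "UTC") {
  n <- max(length(participant_id), length(time), length(color))
  observationLog(tibble::tibble(
    participant_id = rep_len(participant_id, n),
    time = rep_len(time, n), color = rep_len(color, n),
    description = rep_len(description, n),
    observer = rep_len(observer, n)), timezone = tz)
}

# brute-force masked centered moving average (independent oracle)
brute_masked_mean <- function(values, valid, w) {
  n <- length(values)
  before <- (w - 1) %/% 2
  after <- w - 1 - before
  sapply(seq_len(n), function(i) {
    idx <- max(1, i - before):min(n, i + after)
    v <- values[idx][valid[idx]]
    if (!length(v)) NA_real_ else mean(v)
  })
}

# the scaled-down synthetic study used by pipeline-level tests: the study's
# cohort structure (participants, days, incident rates are configurable)
# with shortened wearing windows so many seeds fit in a test run
scaled_cohort_config <- function(...) {
  synthConfig(
    n_participants = 4, n_clinic = 2,
    wearing = list(clinic = c(8, 9), daycare = c(8, 9)),
    incidents = list(red_per_day = 1, orange_per_day = 0.5),
    ibi = list(coverage = 0.02),
    include_bvp = FALSE,
    ...
  )
}
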
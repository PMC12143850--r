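# five clean 2-hour days (08:00-10:00 UTC) for one participant, with
# per-day HR values and optional off-wrist EDA stretches
make_week <- function(pid = "P01", hr_by_day = rep(95, 5),
                      off_wrist_day = NULL, off_span = NULL,
                      config = pipelineConfig()) {
  lapply(1:5, function(d) {
    start <- T0 + (d - 1) * 86400
    s <- make_session(duration_s = 7200, hr = hr_by_day[d], start = start,
                      pid = pid, day = d, with_bvp = FALSE)
    if (!is.null(off_wrist_day) && d == off_wrist_day) {
      tt <- channelTimes(s$channels$EDA)
      w <- tt >= off_span[1] & tt < off_span[2]
      s$channels$EDA$values[w] <- 0
    }
    processSession(s, config)
  })
}

at_day <- function(d, hms) T0 + (d - 1) * 86400 + hms

test_that("incident frames anchor at red onsets; references match clock time", {
  proc <- make_week()
  log <- make_log("P01", at_day(3, 3600), "red")  # day 3, 09:00
  cfg <- pipelineConfig()
  inc <- extractIncidentFrames(log, proc, cfg)
  expect_equal(nrow(inc), 1)
  expect_equal(inc$day_index, 3L)
  expect_equal(inc$start, at_day(3, 3600))
  expect_equal(inc$end - inc$start, 300)
  expect_equal(inc$status, "retained")

  refs <- buildReferenceFrames(inc, proc, log, cfg)
  expect_equal(nrow(refs), 4)                       # days 1, 2, 4, 5
  expect_setequal(refs$day_index, c(1L, 2L, 4L, 5L))
  expect_true(all(refs$status == "retained"))
  # never the incident's own day; same local clock time to the second
  expect_false(3L %in% refs$day_index)
  expect_true(all(refs$start %% 86400 == inc$start %% 86400))

  # orange events are not anchors
  log_o <- make_log("P01", at_day(3, 3600), "orange")
  expect_equal(nrow(extractIncidentFrames(log_o, proc, cfg)), 0)

  # an event outside wearing hours is dropped as missing_data
  log_out <- make_log("P01", at_day(3, 5 * 3600), "red")  # 13:00
  inc_out <- extractIncidentFrames(log_out, proc, cfg)
  expect_equal(inc_out$status, "excluded")
  expect_equal(inc_out$exclusion_reason, "missing_data")
})

test_that("aggression on a reference day excludes that reference", {
  proc <- make_week()
  cfg <- pipelineConfig()
  # incident day 3 09:00; day 2 has a red event at 09:02
  log <- make_log("P01", c(at_day(3, 3600), at_day(2, 3600 + 120)),
                  c("red", "red"))
  inc <- extractIncidentFrames(log, proc, cfg)
  expect_equal(nrow(inc), 2)  # both reds are anchors; take the day-3 one
  inc3 <- inc[inc$day_index == 3L, ]
  refs <- buildReferenceFrames(inc3, proc, log, cfg)
  expect_equal(sum(refs$status == "retained"), 3)
  expect_equal(refs$exclusion_reason[refs$day_index == 2L],
               "aggression_overlap")

  # orange events exclude under the default red+orange rule ...
  log2 <- make_log("P01", c(at_day(3, 3600), at_day(4, 3600 + 60)),
                   c("red", "orange"))
  inc2 <- extractIncidentFrames(log2, proc, cfg)
  refs2 <- buildReferenceFrames(inc2, proc, log2, cfg)
  expect_equal(refs2$exclusion_reason[refs2$day_index == 4L],
               "aggression_overlap")
  # ... but not under the red-only configuration
  cfg_red <- pipelineConfig(frames = list(overlap_colors = "red"))
  refs3 <- buildReferenceFrames(inc2, proc, log2, cfg_red)
  expect_true(all(refs3$status == "retained"))

  # the event-time uncertainty widens the overlap test: an orange event a
  # minute before the window still collides
  log4 <- make_log("P01", c(at_day(3, 3600), at_day(5, 3600 - 60)),
                   c("red", "orange"))
  refs4 <- buildReferenceFrames(extractIncidentFrames(log4, proc, cfg),
                                proc, log4, cfg)
  expect_equal(refs4$exclusion_reason[refs4$day_index == 5L],
               "aggression_overlap")
})

test_that("single-day participants yield no reference candidates", {
  proc <- make_week()[3]
  log <- make_log("P01", at_day(3, 3600), "red")
  inc <- extractIncidentFrames(log, proc, pipelineConfig())
  refs <- buildReferenceFrames(inc, proc, log, pipelineConfig())
  expect_equal(nrow(refs), 0)
  # and such incidents produce no pairs
  pairs <- assemblePairs(dplyr::bind_rows(inc, refs))
  expect_equal(nrow(pairs$hr_bpm), 0)
})

test_that("red events within one merge window share one frame", {
  proc <- make_week()
  log <- make_log("P01", at_day(3, c(3600, 3600 + 120, 3600 + 400)), "red")
  inc <- extractIncidentFrames(log, proc, pipelineConfig())
  # events at +0 s and +120 s merge; +400 s starts its own frame
  expect_equal(nrow(inc), 2)
  expect_equal(sort(inc$start - at_day(3, 3600)), c(0, 400))
})

test_that("the artifact filter excludes strictly above the threshold", {
  base <- make_week()[3]
  log <- make_log("P01", at_day(3, 3600), "red")
  inc <- extractIncidentFrames(log, base, pipelineConfig())
  mk <- function(af) { f <- inc; f$artifact_fraction <- af; f }
  expect_equal(filterArtifactFrames(mk(0.80), 0.75)$exclusion_reason,
               "artifact_gt_75")
  expect_equal(filterArtifactFrames(mk(0.75), 0.75)$status, "retained")
  expect_equal(filterArtifactFrames(mk(0.75 + 1e-9), 0.75)$status, "excluded")
  expect_equal(filterArtifactFrames(mk(0), 0.75)$status, "retained")
  expect_equal(filterArtifactFrames(mk(NA_real_), 0.75)$exclusion_reason,
               "missing_data")
})

test_that("frame summaries are masked means; fully-off-wrist frames are empty", {
  cfg <- pipelineConfig()
  # constant signals: exact means
  proc <- make_week(hr_by_day = rep(95, 5))
  s <- summarizeFrame(proc[[3]], at_day(3, 3600), at_day(3, 3900), cfg)
  expect_equal(s$hr_bpm, 95)
  expect_equal(s$scl_uS, 2)
  expect_equal(s$artifact_fraction, 0)
  expect_equal(s$ppm, 0)
  expect_lt(s$movement_g, 1e-9)

  # HR missing for half the window (off-wrist): mean over the other half.
  # Off-wrist span 08:50-09:02:30 (>=10 min of zero EDA), window 09:00-09:05.
  proc2 <- make_week(hr_by_day = rep(95, 5), off_wrist_day = 3,
                     off_span = c(at_day(3, 3000), at_day(3, 3750)))
  s2 <- summarizeFrame(proc2[[3]], at_day(3, 3600), at_day(3, 3900), cfg)
  expect_equal(s2$hr_bpm, 95)            # valid half only
  expect_equal(s2$artifact_fraction, 0.5)
  # SCL mean over valid epochs only
  expect_equal(s2$scl_uS, 2)

  # fully off-wrist window: all summaries missing
  s3 <- summarizeFrame(proc2[[3]], at_day(3, 3100), at_day(3, 3400), cfg)
  expect_true(is.na(s3$hr_bpm) && is.na(s3$scl_uS) && is.na(s3$movement_g) &&
                is.na(s3$ppm))
  expect_equal(s3$artifact_fraction, 1)
})

test_that("pair assembly drops rows per measure and conserves accounting", {
  proc <- make_week(hr_by_day = c(90, 92, 101, 94, 96))
  cfg <- pipelineConfig()
  log <- make_log("P01", at_day(3, 3600), "red")
  inc <- extractIncidentFrames(log, proc, cfg)
  refs <- buildReferenceFrames(inc, proc, log, cfg)
  ledger <- filterArtifactFrames(dplyr::bind_rows(inc, refs), 0.75)
  pairs <- assemblePairs(ledger)
  expect_equal(nrow(pairs$hr_bpm), 1)
  expect_equal(pairs$hr_bpm$incident, 101)
  expect_equal(pairs$hr_bpm$reference, mean(c(90, 92, 94, 96)))
  expect_equal(pairs$hr_bpm$n_refs, 4)

  # degrees of freedom bookkeeping: 33 pairs -> df 32
  set.seed(4)
  fake <- lapply(1:33, function(i) {
    ref <- rnorm(1, 92, 5)
    tibble::tibble(incident = ref + rnorm(1, 9, 15), reference = ref)
  })
  res <- pairedT(vapply(fake, `[[`, numeric(1), "incident"),
                 vapply(fake, `[[`, numeric(1), "reference"))
  expect_equal(res$df, 32)

  # measure missing on the incident side only: dropped for that measure only
  ledger2 <- ledger
  ledger2$scl_uS[ledger2$kind == "incident"] <- NA_real_
  pairs2 <- assemblePairs(ledger2)
  expect_equal(nrow(pairs2$scl_uS), 0)
  expect_equal(nrow(pairs2$hr_bpm), 1)

  # conservation: every reference is retained or excluded with a reason
  ex <- exclusionSummary(ledger)
  expect_equal(ex$n_candidate_references,
               sum(ledger$kind == "reference"))
  expect_equal(ex$n_retained + ex$n_aggression_overlap +
                 ex$n_artifact_excluded + ex$n_missing_data, nrow(ledger))
})

test_that("ledger percentages reproduce the published exclusion arithmetic", {
  # build a ledger with 192 candidate references of which 35 overlap
  # aggression, and 1723 artifact-checked frames of which 354 exceed 75%
  n_inc <- 48
  inc <- dplyr::bind_rows(lapply(1:n_inc, function(i) tibble::tibble(
    frame_id = sprintf("i%03d", i), incident_id = sprintf("i%03d", i),
    participant_id = "P01", kind = "incident", day_index = 3L,
    start = T0 + i * 1000, end = T0 + i * 1000 + 300,
    artifact_fraction = 0, movement_g = 0, hr_bpm = 95, scl_uS = 2, ppm = 1,
    status = "retained", exclusion_reason = NA_character_)))
  refs <- dplyr::bind_rows(lapply(1:192, function(i) tibble::tibble(
    frame_id = sprintf("r%03d", i), incident_id = sprintf("i%03d", (i %% 48) + 1),
    participant_id = "P01", kind = "reference", day_index = 1L,
    start = T0 + i * 1000, end = T0 + i * 1000 + 300,
    artifact_fraction = 0, movement_g = 0, hr_bpm = 92, scl_uS = 2, ppm = 1,
    status = ifelse(i <= 35, "excluded", "retained"),
    exclusion_reason = ifelse(i <= 35, "aggression_overlap", NA_character_))))
  # pad with extra retained frames so 1723 frames reach artifact checking,
  # then push 354 of them over the threshold
  extra <- dplyr::bind_rows(lapply(1:(1723 - n_inc - (192 - 35)),
                                   function(i) tibble::tibble(
    frame_id = sprintf("x%04d", i), incident_id = sprintf("i%03d", (i %% 48) + 1),
    participant_id = "P02", kind = "reference", day_index = 2L,
    start = T0 + i * 400, end = T0 + i * 400 + 300,
    artifact_fraction = ifelse(i <= 354, 0.8, 0.1),
    movement_g = 0, hr_bpm = 92, scl_uS = 2, ppm = 1,
    status = "retained", exclusion_reason = NA_character_)))
  # overlap accounting on the 192-candidate ledger
  ex1 <- exclusionSummary(filterArtifactFrames(dplyr::bind_rows(inc, refs),
                                               0.75))
  expect_equal(ex1$n_candidate_references, 192)
  expect_equal(ex1$n_aggression_overlap, 35)
  expect_equal(ex1$aggression_overlap_pct, 18.2)
  # artifact accounting on the padded 1723-frame ledger
  ledger <- filterArtifactFrames(dplyr::bind_rows(inc, refs, extra), 0.75)
  ex <- exclusionSummary(ledger)
  expect_equal(ex$n_frames_artifact_checked, 1723)
  expect_equal(ex$n_artifact_excluded, 354)
  expect_equal(ex$artifact_excluded_pct, 20.5)
})
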
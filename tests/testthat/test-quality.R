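# independent brute-force evaluation of the epoch rules
brute_classify <- function(eda_vals, temp_vals, rate = 4, epoch_s = 5,
                           floor = 0.05, ceiling = 60, max_slope = 10,
                           temp_floor = 30) {
  n_epochs <- ceiling(length(eda_vals) / (epoch_s * rate))
  vapply(seq_len(n_epochs), function(k) {
    idx <- ((k - 1) * epoch_s * rate + 1):min(k * epoch_s * rate,
                                              length(eda_vals))
    v <- eda_vals[idx]
    fire <- any(!is.finite(v) | v < floor | v > ceiling)
    # slope attributed to the later sample of each adjacent pair
    for (i in idx) {
      if (i == 1) next
      sl <- abs(eda_vals[i] - eda_vals[i - 1]) * rate
      if (is.finite(sl) && sl > max_slope) fire <- TRUE
    }
    if (!is.null(temp_vals) && any(temp_vals[idx] < temp_floor)) fire <- TRUE
    if (fire) "artifact" else "valid"
  }, character(1))
}

test_that("epoch rules fire on range, slope and temperature violations", {
  eda <- const_channel("EDA", 2, 20, 4)
  temp <- const_channel("TEMP", 33, 20, 4)

  # clean constant signal: every epoch valid
  m <- classifyEdaEpochs(eda, temp)
  expect_true(all(m$label == "valid"))

  # a 0 -> 5 uS jump in one sample is a 20 uS/s slope: artifact
  eda2 <- eda
  eda2$values[30] <- 7  # 2 -> 7 in 0.25 s
  m2 <- classifyEdaEpochs(eda2, temp)
  expect_equal(m2$label[2], "artifact")
  expect_match(m2$rules_fired[2], "slope")
  expect_true(all(m2$label[-2] == "valid"))

  # all-zero record: every epoch artifact via the floor rule
  eda3 <- const_channel("EDA", 0, 20, 4)
  m3 <- classifyEdaEpochs(eda3, temp)
  expect_true(all(m3$label == "artifact"))
  expect_true(all(grepl("range", m3$rules_fired)))

  # cold skin temperature marks the epoch even with clean EDA
  temp2 <- temp
  temp2$values[1:20] <- 25
  m4 <- classifyEdaEpochs(eda, temp2)
  expect_equal(m4$label[1], "artifact")
  expect_match(m4$rules_fired[1], "temp")

  # missing temperature: rule skipped with a warning
  expect_warning(m5 <- classifyEdaEpochs(eda, NULL), "skipped")
  expect_true(all(m5$label == "valid"))

  # empty channel: empty mask
  m6 <- suppressWarnings(
    classifyEdaEpochs(e4Channel("EDA", T0, 4, numeric(0)), NULL))
  expect_equal(nrow(m6), 0)
})

test_that("classification matches the brute-force rule oracle on random signals", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(40:200, 1)
    eda_vals <- runif(n, 0, 3)
    # sprinkle violations of each kind
    eda_vals[sample(n, 2)] <- runif(2, 60, 90)
    eda_vals[sample(n, 2)] <- runif(2, 0, 0.04)
    if (runif(1) < 0.5) eda_vals[sample(2:n, 1)] <- 40  # big jump
    temp_vals <- runif(n, 29, 35)
    eda <- e4Channel("EDA", T0, 4, eda_vals)
    temp <- e4Channel("TEMP", T0, 4, temp_vals)
    m <- classifyEdaEpochs(eda, temp)
    expect_equal(m$label, brute_classify(eda_vals, temp_vals))
  }
})

test_that("long artifact runs become off-wrist; short runs stay artifact", {
  # 12 min artifact run at 5 s epochs (144 epochs) flips to off_wrist at 600 s
  lab <- c(rep("valid", 10), rep("artifact", 144), rep("valid", 10))
  m <- detectOffWrist(make_mask(lab), long_noise_s = 600)
  expect_true(all(m$label[11:154] == "off_wrist"))
  expect_true(all(m$label[c(1:10, 155:164)] == "valid"))

  # 9 min run (108 epochs) stays artifact
  lab2 <- c(rep("valid", 10), rep("artifact", 108), rep("valid", 10))
  m2 <- detectOffWrist(make_mask(lab2), long_noise_s = 600)
  expect_true(all(m2$label[11:118] == "artifact"))

  # alternating epochs never form a long run
  lab3 <- rep(c("valid", "artifact"), 200)
  m3 <- detectOffWrist(make_mask(lab3), long_noise_s = 600)
  expect_false(any(m3$label == "off_wrist"))
})

test_that("off-wrist relabeling is idempotent and never touches valid epochs", {
  set.seed(5)
  for (rep in 1:25) {
    lab <- sample(c("valid", "artifact"), 300, replace = TRUE,
                  prob = c(0.6, 0.4))
    m1 <- detectOffWrist(make_mask(lab), long_noise_s = 120)
    m2 <- detectOffWrist(m1, long_noise_s = 120)
    expect_identical(m1$label, m2$label)
    expect_identical(m1$label == "valid", lab == "valid")
    # labels always partition
    expect_true(all(m1$label %in% c("valid", "artifact", "off_wrist")))
  }
})

test_that("device HR is blanked inside off-wrist spans and only there", {
  hr <- const_channel("HR", 140, 60 * 30, 1)
  lab <- c(rep("valid", 120), rep("artifact", 144), rep("valid", 96))
  m <- detectOffWrist(make_mask(lab), long_noise_s = 600)
  hr2 <- invalidateHrOffWrist(hr, m)
  spans <- offWristSpans(m)
  expect_equal(nrow(spans), 1)
  tt <- channelTimes(hr)
  inside <- tt >= spans$start & tt < spans$end
  expect_true(all(is.na(hr2$values[inside])))
  expect_true(all(hr2$values[!inside] == 140))

  # no off-wrist spans: identity
  m_clean <- make_mask(rep("valid", 100))
  expect_identical(invalidateHrOffWrist(hr, m_clean)$values, hr$values)

  # whole session off-wrist: all missing
  m_all <- detectOffWrist(make_mask(rep("artifact", 360)), 600)
  expect_true(all(is.na(invalidateHrOffWrist(hr, m_all)$values)))
})

test_that("retention accounting reproduces staged hours and percent drops", {
  # one participant: 39.3 h raw, 4.5 h off-wrist, 8.7 h artifact
  # -> 34.8 h after long noise (-11%), 26.1 h after artifacts (-25%)
  ep <- function(h) round(h * 3600 / 5)
  lab <- c(rep("off_wrist", ep(4.5)), rep("artifact", ep(8.7)),
           rep("valid", ep(26.1)))
  m <- make_mask(lab)
  rep1 <- retentionReport(list(m), "P01")
  expect_equal(rep1$average$raw_hours, 39.3, tolerance = 1e-6)
  expect_equal(rep1$average$hours_after_long_noise, 34.8, tolerance = 1e-6)
  expect_equal(rep1$average$reduction_long_noise_pct, 11)
  expect_equal(rep1$average$hours_after_artifacts, 26.1, tolerance = 1e-6)
  expect_equal(rep1$average$reduction_artifact_pct, 25)

  # all-valid session: zero reductions
  rep2 <- retentionReport(list(make_mask(rep("valid", 720))), "P02")
  expect_equal(rep2$average$reduction_long_noise_pct, 0)
  expect_equal(rep2$average$reduction_artifact_pct, 0)
})

test_that("retention is monotone for every participant on random masks", {
  set.seed(9)
  masks <- lapply(1:12, function(i)
    make_mask(sample(c("valid", "artifact", "off_wrist"), 500, replace = TRUE)))
  rep <- retentionReport(masks, rep(sprintf("P%02d", 1:4), each = 3))
  with(rep$by_participant, {
    expect_true(all(raw_hours >= hours_after_long_noise))
    expect_true(all(hours_after_long_noise >= hours_after_artifacts))
  })
})

test_that("mask CSV export carries epochs, labels and fired rules", {
  eda <- const_channel("EDA", 0, 20, 4)
  m <- suppressWarnings(classifyEdaEpochs(eda, NULL))
  f <- withr::local_tempfile(fileext = ".csv")
  writeQualityMask(m, f)
  got <- read.csv(f)
  expect_equal(nrow(got), 4)
  expect_true(all(got$label == "artifact"))
  expect_true(all(got$rules_fired == "range"))
})
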
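test_that("zero-amplitude profile yields pure gravity and silent gyroscope", {
  prof <- subject_profile("z", 1.25, base_impact_g = 1e-12,
                          base_swing_dps = 1e-12, noise_sd = 0)
  rec <- generate_recording(prof, list(stage_effect("Pre")), 5, "LL", 1)
  expect_lt(max(abs(rec$gyr)), 1e-6)
  expect_equal(rec$acc[, 3], rep(1, nrow(rec$acc)), tolerance = 1e-6)
  expect_lt(max(abs(rec$acc[, 1:2])), 1e-6)
})

test_that("stage durations map exactly onto sample counts and labels", {
  rec <- tiny_recording()
  expect_equal(nrow(rec$acc), 6000)
  expect_equal(as.integer(table(rec$stage_labels)), c(2000, 2000, 2000))
  expect_equal(levels(rec$stage_labels), c("Pre", "Mid", "Post"))
  # acc, gyr, mag, labels share the leading length
  expect_equal(nrow(rec$gyr), 6000)
  expect_equal(nrow(rec$mag), 6000)
  # instrument ranges respected
  expect_true(all(abs(rec$acc) <= 16))
  expect_true(all(abs(rec$gyr) <= 500))
})

test_that("impact peak count in a 10 s segment matches stride frequency", {
  rec <- tiny_recording(noise_sd = 0)
  az <- rec$acc[1:2000, 3]
  thr <- 3 / 2                       # half the configured impact amplitude
  peaks <- sum(diff(sign(diff(az))) == -2 & az[2:1999] > thr)
  # 10 s at 1.25 cycles/s -> 12 or 13 foot strikes
  expect_true(peaks %in% c(12L, 13L))
})

test_that("identical arguments reproduce a recording bitwise", {
  a <- tiny_recording(noise_sd = 1, seed = 42)
  b <- tiny_recording(noise_sd = 1, seed = 42)
  expect_identical(a$acc, b$acc)
  expect_identical(a$gyr, b$gyr)
  expect_identical(a$mag, b$mag)
  c <- tiny_recording(noise_sd = 1, seed = 43)
  expect_false(identical(a$acc, c$acc))
})

test_that("impact scale monotonically raises the mean vertical-acc peak", {
  peak_mean <- function(impact_scale) {
    eff <- list(stage_effect("Pre", impact_scale = impact_scale))
    rec <- generate_recording(quiet_profile(0), eff, 10, "LL", 1)
    az <- rec$acc[, 3]
    idx <- which(diff(sign(diff(az))) == -2) + 1L
    mean(az[idx[az[idx] > stats::median(az)]])
  }
  p <- vapply(c(0.5, 1, 1.5, 2), peak_mean, 1)
  expect_true(all(diff(p) > 0))
})

test_that("cohort size equals subjects x sites and is seed-reproducible", {
  recs <- generate_cohort(1, "LL", seed = 2, stage_durations_s = c(2, 2, 2))
  expect_length(recs, 1L)
  recs3 <- generate_cohort(19, c("LL", "UL", "PEL"), seed = 2,
                           stage_durations_s = c(1, 1, 1))
  expect_length(recs3, 57L)
  again <- generate_cohort(19, c("LL", "UL", "PEL"), seed = 2,
                           stage_durations_s = c(1, 1, 1))
  expect_identical(
    lapply(recs3, function(r) r$acc),
    lapply(again, function(r) r$acc))
  expect_error(generate_cohort(2, character(0)), "sites")
  expect_error(generate_cohort(0, "LL"), "n_subjects")
})

test_that("invalid recording arguments are rejected", {
  prof <- quiet_profile()
  expect_error(generate_recording(prof, default_stage_effects(),
                                  c(10, -5, 10), "LL", 1), "positive")
  expect_error(generate_recording(prof, default_stage_effects(),
                                  c(10, 10, 10), "ANKLE", 1), "site")
  expect_error(generate_recording(prof, default_stage_effects(),
                                  c(10, 10), "LL", 1), "equal length")
  expect_error(subject_profile("x", stride_frequency_hz = 3), "0.5, 2.5")
  expect_error(subject_profile("x", noise_sd = -1), "noise_sd")
})

test_that("stage metadata follows the per-stage RPE/HR distributions", {
  draws <- t(vapply(1:200, function(i) {
    rec <- generate_recording(quiet_profile(1), default_stage_effects(),
                              c(0.2, 0.2, 0.2), "LL", seed = i)
    rec$stage_meta$rpe
  }, numeric(3)))
  means <- colMeans(draws)
  expect_equal(means, c(6.6, 11.9, 15.2), tolerance = 0.05)
  expect_true(all(diff(means) > 0))
})

test_that("recordings round-trip through the CSV schema", {
  rec <- tiny_recording(noise_sd = 1, durations = c(2, 2, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path, subject_id = rec$subject_id,
                             site = rec$site)
  expect_equal(back$acc, rec$acc, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$gyr, rec$gyr, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.character(back$stage_labels),
               as.character(rec$stage_labels))
  expect_equal(back$fs_hz, rec$fs_hz, tolerance = 1e-6)
})

test_that("default effects keep stages separable by a linear classifier", {
  recs <- generate_cohort(3, "LL", seed = 9,
                          stage_durations_s = c(15, 15, 15))
  sets <- lapply(recs, function(r) {
    segment_windows(select_channels(r, combo = "ACC_GYR"),
                    r$stage_labels, windowing_config(),
                    channel_combo("ACC_GYR"), r$subject_id, r$site)
  })
  ws <- bind_window_sets(sets)
  # per-window RMS per channel as features
  feats <- t(apply(ws$windows, 1, function(w) sqrt(colMeans(w^2))))
  df <- data.frame(feats, stage = ws$labels)
  fit <- nnet::multinom(stage ~ ., df, trace = FALSE)
  acc <- mean(predict(fit) == df$stage)
  expect_gt(acc, 1 / 3)
})
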
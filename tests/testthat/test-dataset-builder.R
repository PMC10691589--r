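test_that("channel combinations select the documented columns", {
  rec <- tiny_recording(durations = c(3, 3, 3))
  expect_equal(channel_combo("ACC")$dim, 3L)
  expect_equal(channel_combo("GYR")$dim, 3L)
  expect_equal(channel_combo("ACC_GYR")$dim, 6L)
  expect_equal(channel_combo("ACC_GYR_POS")$dim, 9L)

  acc_only <- select_channels(rec, combo = "ACC")
  expect_equal(ncol(acc_only), 3L)
  expect_equal(unname(acc_only), unname(rec$acc))

  both <- select_channels(rec, combo = "ACC_GYR")
  expect_equal(colnames(both), c("ax", "ay", "az", "gx", "gy", "gz"))

  orient <- estimate_orientation(rec$acc, rec$gyr, rec$mag, rec$fs_hz)
  full <- select_channels(rec, orient, "ACC_GYR_POS")
  expect_equal(ncol(full), 9L)
  expect_equal(unname(full[, 7:9]), unname(orient$euler_deg))
  expect_error(select_channels(rec, NULL, "ACC_GYR_POS"), "orientation")

  # a silent gyroscope propagates into zero gyro columns
  prof <- subject_profile("z", 1.25, base_impact_g = 1,
                          base_swing_dps = 1e-12, noise_sd = 0)
  rz <- generate_recording(prof, list(stage_effect("Pre")), 3, "LL", 1)
  sel <- select_channels(rz, combo = "ACC_GYR")
  expect_lt(max(abs(sel[, 4:6])), 1e-6)
})

test_that("window counts follow floor((L - Nc)/step) + 1 per segment", {
  D <- 2
  mk <- function(L) matrix(stats::rnorm(L * D), ncol = D)
  lab <- function(stage, L) rep(stage, L)

  # single segment of exactly one window length
  for (ov in c(0, 0.5)) {
    ws <- segment_windows(mk(200), lab("Pre", 200),
                          windowing_config(overlap_fraction = ov))
    expect_equal(dim(ws$windows)[1], 1L)
  }
  # L = 1000: 5 windows at step 200, 9 at step 100
  ws0 <- segment_windows(mk(1000), lab("Mid", 1000),
                         windowing_config(overlap_fraction = 0))
  expect_equal(dim(ws0$windows)[1], 5L)
  ws5 <- segment_windows(mk(1000), lab("Mid", 1000),
                         windowing_config(overlap_fraction = 0.5))
  expect_equal(dim(ws5$windows)[1], 9L)

  # windows never straddle a stage boundary
  series <- mk(600)
  labels <- c(lab("Pre", 300), lab("Mid", 300))
  ws <- segment_windows(series, labels,
                        windowing_config(overlap_fraction = 0.5))
  expect_equal(dim(ws$windows)[1], 4L)
  expect_equal(as.integer(table(ws$labels)), c(2L, 2L, 0L))
  expect_true(all(ws$provenance$start_index %in% c(1, 101, 301, 401)))

  # window content is the raw slice, untouched
  expect_equal(ws$windows[3, , ], series[301:500, ])
})

test_that("50% overlap doubles the count minus one on aligned segments", {
  D <- 1
  for (L in c(1000, 2200, 4000)) {     # (L - 200) multiples of 200
    x <- matrix(stats::rnorm(L), ncol = 1)
    n0 <- dim(segment_windows(x, rep("Pre", L),
      windowing_config(overlap_fraction = 0))$windows)[1]
    n5 <- dim(segment_windows(x, rep("Pre", L),
      windowing_config(overlap_fraction = 0.5))$windows)[1]
    expect_equal(n5, 2L * n0 - 1L)
  }
})

test_that("too-short segments yield an empty set with a warning", {
  x <- matrix(stats::rnorm(150 * 2), ncol = 2)
  expect_warning(
    ws <- segment_windows(x, rep("Pre", 150), windowing_config()),
    "no labeled segment")
  expect_equal(dim(ws$windows)[1], 0L)
})

test_that("windowing configuration enforces the cycle-coverage rule", {
  expect_error(windowing_config(window_len = 150, fs_hz = 200,
                                min_cycle_s = 1), "gait cycle")
  expect_error(windowing_config(overlap_fraction = 1), "overlap")
  expect_silent(windowing_config(window_len = 200, overlap_fraction = 0))
  expect_equal(windowing_config(overlap_fraction = 0.5)$step, 100L)
  expect_equal(windowing_config(overlap_fraction = 0)$step, 200L)
})

test_that("shuffle_split produces a deterministic 72/18/10 partition", {
  ws <- small_window_set()
  N <- dim(ws$windows)[1]
  sp <- shuffle_split(ws, seed = 31)
  n_test <- floor(0.10 * N); n_val <- floor(0.18 * N)
  expect_equal(dim(sp$test$windows)[1], n_test)
  expect_equal(dim(sp$val$windows)[1], n_val)
  expect_equal(dim(sp$train$windows)[1], N - n_test - n_val)
  # partition: each provenance row lands in exactly one split
  key <- function(s) paste(s$provenance$subject_id, s$provenance$site,
                           s$provenance$start_index)
  all_keys <- c(key(sp$train), key(sp$val), key(sp$test))
  expect_equal(sort(all_keys), sort(key(ws)))
  expect_equal(anyDuplicated(all_keys), 0L)
  # determinism
  sp2 <- shuffle_split(ws, seed = 31)
  expect_identical(sp$train$labels, sp2$train$labels)
  expect_identical(sp$test$provenance, sp2$test$provenance)
  # proportions land within one window of the nominal 72/18/10
  expect_lte(abs(n_test - 0.10 * N), 1)
  expect_lte(abs(n_val - 0.18 * N), 1)
})

test_that("a 100-window set splits exactly 72/18/10", {
  ws <- small_window_set()
  ws100 <- ns$take_windows(ws, 1:100)
  sp <- shuffle_split(ws100, seed = 1)
  expect_equal(vapply(list(sp$train, sp$val, sp$test),
                      function(s) dim(s$windows)[1], 1L),
               c(72L, 18L, 10L))
})

test_that("splitting requires at least ten windows", {
  ws <- small_window_set()
  expect_error(shuffle_split(ns$take_windows(ws, 1:9), 1), "at least 10")
})

test_that("subject-level splitting keeps subjects disjoint", {
  recs <- generate_cohort(10, "LL", seed = 3,
                          stage_durations_s = c(3, 3, 3))
  sets <- lapply(recs, function(r)
    segment_windows(select_channels(r, combo = "ACC"), r$stage_labels,
                    windowing_config(), channel_combo("ACC"),
                    r$subject_id, r$site))
  ws <- bind_window_sets(sets)
  sp <- shuffle_split(ws, seed = 4, by_subject = TRUE)
  subj <- function(s) unique(s$provenance$subject_id)
  expect_length(intersect(subj(sp$train), subj(sp$test)), 0L)
  expect_length(intersect(subj(sp$train), subj(sp$val)), 0L)
  expect_length(intersect(subj(sp$val), subj(sp$test)), 0L)
})

test_that("window archives reload bit-exactly with their sidecar", {
  ws <- small_window_set()
  path <- withr::local_tempfile(fileext = ".rds")
  write_window_archive(ws, path)
  back <- read_window_archive(path)
  expect_identical(back$windows, ws$windows)
  expect_identical(back$labels, ws$labels)
  sidecar <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(sidecar$combo, ws$combo$name)
  expect_equal(sidecar$n_windows, dim(ws$windows)[1])
})
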
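# Small deterministic fixtures shared across test files. Everything is
# generated in code; nothing is read from disk.

quiet_profile <- function(noise_sd = 0, stride = 1.25) {
  subject_profile("T01", stride_frequency_hz = stride,
                  base_impact_g = 3, base_swing_dps = 200,
                  noise_sd = noise_sd)
}

# One short three-stage recording (10 s per stage at 200 Hz).
tiny_recording <- function(noise_sd = 0, site = "LL", seed = 7,
                           durations = c(10, 10, 10)) {
  generate_recording(quiet_profile(noise_sd), default_stage_effects(),
                     durations, site, seed = seed)
}

# A small pooled window set from a 2-subject cohort, for split tests
# (114 windows: 19 per stage, 3 stages, 2 subjects).
small_window_set <- function(seed = 5, combo = "ACC_GYR") {
  recs <- generate_cohort(2, "LL", seed = seed,
                          stage_durations_s = c(10, 10, 10))
  sets <- lapply(recs, function(r) {
    segment_windows(select_channels(r, combo = combo), r$stage_labels,
                    windowing_config(overlap_fraction = 0.5),
                    channel_combo(combo),
                    subject_id = r$subject_id, site = r$site)
  })
  bind_window_sets(sets)
}

# Miniature split set with random windows, for engine/training tests
# where the data content does not matter.
random_splits <- function(n = 40, len = 12, d = 3, seed = 3) {
  withr::with_seed(seed, {
    ws <- structure(list(
      windows = array(stats::rnorm(n * len * d), c(n, len, d)),
      labels = factor(sample(c("Pre", "Mid", "Post"), n, replace = TRUE),
                      levels = c("Pre", "Mid", "Post")),
      combo = channel_combo("ACC"), cfg = NULL,
      provenance = data.frame(subject_id = rep("x", n), site = "LL",
                              start_index = seq_len(n))),
      class = "window_set")
    shuffle_split(ws, seed = seed)
  })
}

# Test double: a "model" that predicts a fixed label vector, used to
# check the evaluation arithmetic independently of any training.
scripted_predictor <- function(labels) {
  structure(list(fixed = labels), class = "scripted_predictor")
}
predict.scripted_predictor <- function(object, newdata, ...) object$fixed
registerS3method("predict", "scripted_predictor",
                 predict.scripted_predictor, envir = globalenv())

ns <- asNamespace("runfatigue")
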
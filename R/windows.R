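# Window dataset construction: per-sample feature composition
# x = (ACC, GYR, POS), constant-length sliding-window segmentation with
# configurable overlap, and shuffled 72/18/10 splitting.

COMBOS <- list(ACC = 3L, GYR = 3L, ACC_GYR = 6L, ACC_GYR_POS = 9L)

#' Channel combination descriptor
#'
#' @param name One of `"ACC"`, `"GYR"`, `"ACC_GYR"`, `"ACC_GYR_POS"`.
#' @return An object of class `channel_combo` with fields `name` and `dim`
#'   (3, 3, 6 or 9).
#' @export
channel_combo <- function(name = c("ACC_GYR", "ACC", "GYR", "ACC_GYR_POS")) {
  name <- match.arg(name)
  structure(list(name = name, dim = COMBOS[[name]]), class = "channel_combo")
}

#' Windowing configuration
#'
#' The window length must cover at least one gait cycle:
#' `window_len >= fs_hz * min_cycle_s`. The step between consecutive
#' windows is `round(window_len * (1 - overlap_fraction))`.
#'
#' @param window_len Window length in samples (default 200, i.e. 1 s at
#'   200 Hz).
#' @param overlap_fraction Fraction of overlap in \[0, 1); the study design
#'   uses 0 (step 200) or 0.5 (step 100).
#' @param fs_hz Sampling frequency.
#' @param min_cycle_s Longest admissible gait cycle (seconds).
#' @return An object of class `windowing_config` with derived field `step`.
#' @export
windowing_config <- function(window_len = 200, overlap_fraction = 0.5,
                             fs_hz = 200, min_cycle_s = 1) {
  check_positive(window_len, "window_len")
  check_positive(fs_hz, "fs_hz")
  check_positive(min_cycle_s, "min_cycle_s")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop_invalid("overlap_fraction must lie in [0, 1)")
  if (window_len < fs_hz * min_cycle_s)
    stop_invalid("window_len must satisfy window_len >= fs_hz * min_cycle_s ",
                 "(one full gait cycle per window)")
  step <- as.integer(round(window_len * (1 - overlap_fraction)))
  if (step < 1L) stop_invalid("derived step must be >= 1")
  structure(list(window_len = as.integer(window_len),
                 overlap_fraction = overlap_fraction,
                 fs_hz = fs_hz, min_cycle_s = min_cycle_s, step = step),
            class = "windowing_config")
}

#' Compose the per-sample feature matrix for a channel combination
#'
#' Column order is `(ax, ay, az[, gx, gy, gz[, px, py, pz]])`; the GYR
#' combo yields `(gx, gy, gz)` alone.
#'
#' @param recording An `imu_recording` (optionally filtered).
#' @param orientation An `orientation_series` aligned with the recording;
#'   required for `ACC_GYR_POS`.
#' @param combo A [channel_combo()] or combo name.
#' @return T x D numeric matrix, D = `combo$dim`.
#' @export
select_channels <- function(recording, orientation = NULL,
                            combo = channel_combo("ACC_GYR")) {
  stopifnot(inherits(recording, "imu_recording"))
  if (is.character(combo)) combo <- channel_combo(combo)
  out <- switch(combo$name,
    ACC = recording$acc,
    GYR = recording$gyr,
    ACC_GYR = cbind(recording$acc, recording$gyr),
    ACC_GYR_POS = {
      if (is.null(orientation))
        stop_invalid("combo ACC_GYR_POS requires an orientation series")
      eul <- orientation$euler_deg
      if (nrow(eul) != nrow(recording$acc))
        stop_invalid("orientation length must match the recording")
      cbind(recording$acc, recording$gyr, eul)
    })
  colnames(out) <- c("ax", "ay", "az", "gx", "gy", "gz",
                     "px", "py", "pz")[switch(combo$name,
                       ACC = 1:3, GYR = 4:6, ACC_GYR = 1:6,
                       ACC_GYR_POS = 1:9)]
  out
}

#' Segment a labeled series into constant-length windows
#'
#' Windows are taken per contiguous same-label segment, starting at
#' multiples of the step from the segment start; a segment shorter than
#' the window contributes nothing, and no window ever straddles a stage
#' boundary. Each labeled segment of length `L >= Nc` yields
#' `floor((L - Nc) / step) + 1` windows.
#'
#' @param series T x D numeric matrix.
#' @param labels Length-T stage labels (`Pre`/`Mid`/`Post`).
#' @param cfg A [windowing_config()].
#' @param combo Channel combination recorded for provenance.
#' @param subject_id,site Optional provenance.
#' @return An object of class `window_set`: `windows` (N x Nc x D array),
#'   `labels` (factor length N), `combo`, `cfg`, `provenance` (data frame
#'   with `subject_id`, `site`, `start_index`).
#' @export
segment_windows <- function(series, labels, cfg = windowing_config(),
                            combo = channel_combo("ACC_GYR"),
                            subject_id = NA_character_,
                            site = NA_character_) {
  series <- as.matrix(series)
  stopifnot(inherits(cfg, "windowing_config"))
  if (is.character(combo)) combo <- channel_combo(combo)
  if (nrow(series) != length(labels))
    stop_invalid("labels must align with the series rows")
  labels <- as_stage_factor(labels)
  Nc <- cfg$window_len; step <- cfg$step; D <- ncol(series)

  runs <- rle(as.integer(labels))
  seg_end <- cumsum(runs$lengths)
  seg_start <- seg_end - runs$lengths + 1L

  starts <- integer(0); win_lab <- integer(0)
  for (k in seq_along(runs$lengths)) {
    L <- runs$lengths[k]
    if (L < Nc) next
    s <- seq.int(seg_start[k], seg_start[k] + L - Nc, by = step)
    starts <- c(starts, s)
    win_lab <- c(win_lab, rep(runs$values[k], length(s)))
  }
  N <- length(starts)
  if (N == 0L)
    warning("no labeled segment is long enough for a full window",
            call. = FALSE)
  win <- array(0, dim = c(N, Nc, D))
  for (i in seq_len(N))
    win[i, , ] <- series[starts[i] + 0:(Nc - 1L), , drop = FALSE]
  structure(list(
    windows = win,
    labels = factor(STAGES[win_lab], levels = STAGES),
    combo = combo, cfg = cfg,
    provenance = data.frame(subject_id = rep(subject_id, N),
                            site = rep(site, N),
                            start_index = starts)),
    class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d x %d (%s)\n",
              dim(x$windows)[1], dim(x$windows)[2], dim(x$windows)[3],
              x$combo$name))
  print(table(x$labels))
  invisible(x)
}

#' Concatenate window sets
#'
#' @param sets List of `window_set`s with identical window shape and combo.
#' @return A single `window_set`.
#' @export
bind_window_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  d <- dim(sets[[1]]$windows)[-1]
  N <- sum(vapply(sets, function(s) dim(s$windows)[1], 1L))
  win <- array(0, dim = c(N, d))
  at <- 0L
  for (s in sets) {
    n <- dim(s$windows)[1]
    if (n > 0) win[at + seq_len(n), , ] <- s$windows
    at <- at + n
  }
  structure(list(windows = win,
                 labels = factor(unlist(lapply(sets, function(s)
                   as.character(s$labels))), levels = STAGES),
                 combo = sets[[1]]$combo, cfg = sets[[1]]$cfg,
                 provenance = do.call(rbind,
                   lapply(sets, function(s) s$provenance))),
            class = "window_set")
}

take_windows <- function(ws, idx) {
  structure(list(windows = ws$windows[idx, , , drop = FALSE],
                 labels = ws$labels[idx],
                 combo = ws$combo, cfg = ws$cfg,
                 provenance = ws$provenance[idx, , drop = FALSE]),
            class = "window_set")
}

#' Shuffle and split windows 72/18/10
#'
#' Randomly permutes the pooled windows by `seed`, holds out
#' `floor(0.10 N)` for test, then splits the remainder 80/20 into
#' training (72% of all) and validation (18% of all). The split is at
#' window granularity (pooled shuffle); with `by_subject = TRUE` whole
#' subjects are assigned to splits instead, which avoids subject leakage
#' at the cost of coarser proportions.
#'
#' @param ws A `window_set` with at least 10 windows.
#' @param seed Integer seed.
#' @param by_subject Split at subject granularity (default `FALSE`).
#' @return An object of class `split_set`: list with `train`, `val`,
#'   `test` window sets and `seed`.
#' @export
shuffle_split <- function(ws, seed = 1, by_subject = FALSE) {
  stopifnot(inherits(ws, "window_set"))
  N <- dim(ws$windows)[1]
  if (N < 10) stop_invalid("need at least 10 windows to split")
  idx <- if (by_subject) {
    subj <- ws$provenance$subject_id
    us <- unique(subj)
    ord <- with_seed(seed, sample(us))
    n_test <- max(1L, floor(0.10 * length(us)))
    n_val <- max(1L, floor(0.18 * length(us)))
    list(test = which(subj %in% ord[seq_len(n_test)]),
         val = which(subj %in% ord[n_test + seq_len(n_val)]),
         train = which(subj %in% ord[-seq_len(n_test + n_val)]))
  } else {
    perm <- with_seed(seed, sample.int(N))
    n_test <- floor(0.10 * N)
    n_val <- floor(0.18 * N)
    list(test = perm[seq_len(n_test)],
         val = perm[n_test + seq_len(n_val)],
         train = perm[(n_test + n_val + 1L):N])
  }
  structure(list(train = take_windows(ws, idx$train),
                 val = take_windows(ws, idx$val),
                 test = take_windows(ws, idx$test),
                 seed = as.integer(seed)),
            class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat(sprintf("<split_set> train %d / val %d / test %d windows (seed %d)\n",
              dim(x$train$windows)[1], dim(x$val$windows)[1],
              dim(x$test$windows)[1], x$seed))
  invisible(x)
}

#' Save / load a window archive
#'
#' The tensor goes to an RDS archive and the configuration (combo,
#' windowing parameters, seed) to a JSON sidecar for bit-exact reload.
#'
#' @param ws A `window_set`.
#' @param path Archive path (`.rds`); the sidecar is `path` + `.json`.
#' @return `path` invisibly, or the reloaded `window_set`.
#' @export
write_window_archive <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  saveRDS(ws, path)
  sidecar <- list(combo = ws$combo$name,
                  window_len = ws$cfg$window_len,
                  overlap_fraction = ws$cfg$overlap_fraction,
                  fs_hz = ws$cfg$fs_hz,
                  n_windows = dim(ws$windows)[1])
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_window_archive
#' @export
read_window_archive <- function(path) {
  ws <- readRDS(path)
  stopifnot(inherits(ws, "window_set"))
  ws
}
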
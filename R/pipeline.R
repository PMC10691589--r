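# Config-driven orchestration: simulate -> filter -> orientation ->
# window -> split -> train -> evaluate, with deterministic seeds and
# re-readable artifacts.

#' Default pipeline configuration
#'
#' @return Nested list with blocks `synthetic`, `filter`, `windowing`,
#'   `train`, plus `model`, `seed` and `output_dir`.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    model = "CNN",
    synthetic = list(n_subjects = 6L, sites = "LL",
                     stage_durations_s = c(20, 20, 20), noise_sd = 1),
    filter = list(apply = TRUE, order = 4L, cutoff_hz = 15,
                  zero_phase = FALSE),
    windowing = list(window_len = 200L, overlap = 0.5,
                     combo = "ACC_GYR", site = "LL"),
    train = list(batch_size = 256L, max_epochs = 30L,
                 early_stop_patience = 14L, monitor = "val_loss",
                 learning_rate = 1e-3))
}

merge_config <- function(base, extra) {
  for (nm in names(extra)) {
    if (is.list(base[[nm]]) && is.list(extra[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], extra[[nm]])
    else base[[nm]] <- extra[[nm]]
  }
  base
}

#' Read, validate and complete a pipeline configuration
#'
#' @param config Path to a YAML file, or a nested list; missing entries
#'   are filled from [default_pipeline_config()].
#' @param ... Named overrides applied last: `seed`, `model`, `combo`,
#'   `overlap`, `site`, `output_dir`.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  cfg <- merge_config(default_pipeline_config(), config)
  if (!"output_dir" %in% names(cfg)) cfg["output_dir"] <- list(NULL)
  ov <- list(...)
  if (!is.null(ov$seed)) cfg$seed <- ov$seed
  if (!is.null(ov$model)) cfg$model <- ov$model
  if (!is.null(ov$combo)) cfg$windowing$combo <- ov$combo
  if (!is.null(ov$overlap)) cfg$windowing$overlap <- ov$overlap
  if (!is.null(ov$site)) cfg$windowing$site <- ov$site
  if (!is.null(ov$output_dir)) cfg$output_dir <- ov$output_dir

  bad <- character(0)
  if (!cfg$model %in% MODEL_NAMES) bad <- c(bad, "model")
  if (!cfg$windowing$combo %in% names(COMBOS)) bad <- c(bad, "windowing.combo")
  if (!cfg$windowing$site %in% SITES) bad <- c(bad, "windowing.site")
  if (!all(cfg$synthetic$sites %in% SITES)) bad <- c(bad, "synthetic.sites")
  if (cfg$windowing$overlap < 0 || cfg$windowing$overlap >= 1)
    bad <- c(bad, "windowing.overlap")
  if (!cfg$train$monitor %in% c("val_loss", "train_loss"))
    bad <- c(bad, "train.monitor")
  if (!cfg$windowing$site %in% cfg$synthetic$sites)
    bad <- c(bad, "windowing.site (not among simulated sites)")
  if (length(bad))
    stop_invalid("invalid pipeline configuration keys: ",
                 paste(bad, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Recordings -> pooled, labeled window set per the configuration.
build_windows_from_recordings <- function(recs, cfg) {
  fcfg <- filter_config(order = cfg$filter$order,
                        cutoff_hz = cfg$filter$cutoff_hz,
                        zero_phase = isTRUE(cfg$filter$zero_phase))
  combo <- channel_combo(cfg$windowing$combo)
  wcfg <- windowing_config(window_len = cfg$windowing$window_len,
                           overlap_fraction = cfg$windowing$overlap)
  sets <- lapply(recs, function(rec) {
    orient <- NULL
    if (combo$name == "ACC_GYR_POS")
      orient <- estimate_orientation(rec$acc, rec$gyr, rec$mag, rec$fs_hz)
    work <- rec
    if (isTRUE(cfg$filter$apply)) {
      work$acc <- lowpass_filter(rec$acc, fcfg)
      work$gyr <- lowpass_filter(rec$gyr, fcfg)
    }
    series <- select_channels(work, orient, combo)
    segment_windows(series, rec$stage_labels, wcfg, combo,
                    subject_id = rec$subject_id, site = rec$site)
  })
  bind_window_sets(sets)
}

#' Run the full pipeline from a configuration
#'
#' Simulates the synthetic cohort, conditions the signals, builds and
#' splits the window dataset, trains the configured model and evaluates
#' it on the held-out test split. When `output_dir` is set, artifacts are
#' written there: recording CSVs, the window archive (+ JSON sidecar),
#' the model specification JSON, the evaluation report JSON, the
#' confusion matrix CSV and the training history CSV.
#'
#' @param config Path, list or `pipeline_config`.
#' @param ... Overrides forwarded to [pipeline_config()].
#' @param verbose Print progress.
#' @return Invisibly, a list with `model`, `report`, `splits`, `config`,
#'   and `paths` (written artifacts, if any).
#' @export
run_pipeline <- function(config = list(), ..., verbose = FALSE) {
  cfg <- pipeline_config(config, ...)
  out <- cfg$output_dir
  paths <- list()
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)

  recs <- generate_cohort(cfg$synthetic$n_subjects, cfg$synthetic$sites,
                          seed = cfg$seed,
                          stage_durations_s = cfg$synthetic$stage_durations_s,
                          noise_sd = cfg$synthetic$noise_sd)
  recs <- Filter(function(r) r$site == cfg$windowing$site, recs)
  if (!is.null(out)) {
    paths$recordings <- vapply(recs, function(r) {
      p <- file.path(out, sprintf("recording_%s_%s.csv", r$subject_id,
                                  r$site))
      write_recording_csv(r, p)
      p
    }, character(1))
  }

  ws <- build_windows_from_recordings(recs, cfg)
  splits <- shuffle_split(ws, seed = cfg$seed)
  if (verbose) print(splits)
  if (!is.null(out)) {
    paths$windows <- file.path(out, "windows.rds")
    write_window_archive(ws, paths$windows)
  }

  spec <- build_model(cfg$model, input_len = cfg$windowing$window_len,
                      input_dim = ws$combo$dim)
  if (!is.null(out)) {
    paths$model_spec <- file.path(out, "model_spec.json")
    model_spec_to_json(spec, paths$model_spec)
  }

  ctrl <- train_control(batch_size = cfg$train$batch_size,
                        max_epochs = cfg$train$max_epochs,
                        early_stop_patience = cfg$train$early_stop_patience,
                        monitor = cfg$train$monitor,
                        learning_rate = cfg$train$learning_rate,
                        seed = cfg$seed)
  model <- fit_fatigue_model(spec, splits, ctrl, verbose = verbose)
  report <- evaluate(model, splits$test)
  if (!is.null(out)) {
    paths$report <- file.path(out, "eval_report.json")
    eval_report_to_json(report, paths$report)
    paths$confusion <- file.path(out, "confusion.csv")
    utils::write.csv(as.data.frame.matrix(report$confusion),
                     paths$confusion)
    paths$history <- file.path(out, "history.csv")
    utils::write.csv(model$history, paths$history, row.names = FALSE)
    paths$config <- file.path(out, "config.yaml")
    write_pipeline_config(cfg, paths$config)
  }
  invisible(list(model = model, report = report, splits = splits,
                 config = cfg, paths = paths))
}

#' Compare models across seeds on identical splits
#'
#' For each repeat a fresh seed is derived from `config$seed`; all models
#' in that repeat share the same simulated data and split and differ only
#' in architecture (and their own initialization stream).
#'
#' @param config Path, list or `pipeline_config`.
#' @param models Character vector of model names.
#' @param n_seeds Number of repeats (>= 1).
#' @param ... Overrides forwarded to [pipeline_config()].
#' @return Data frame with one row per model: mean and SD of test
#'   accuracy over the repeats. The per-run accuracies are attached as
#'   attribute `"runs"`.
#' @export
compare_models <- function(config = list(), models = MODEL_NAMES,
                           n_seeds = 1, ...) {
  cfg <- pipeline_config(config, ...)
  if (n_seeds < 1) stop_invalid("n_seeds must be >= 1")
  models <- vapply(models, function(m) match.arg(m, MODEL_NAMES),
                   character(1), USE.NAMES = FALSE)
  runs <- expand.grid(model = models, rep = seq_len(n_seeds),
                      stringsAsFactors = FALSE)
  runs$accuracy <- NA_real_
  for (r in seq_len(n_seeds)) {
    seed_r <- if (n_seeds == 1) cfg$seed else derive_seed(cfg$seed, r)
    for (m in models) {
      res <- run_pipeline(cfg, model = m, seed = seed_r)
      runs$accuracy[runs$model == m & runs$rep == r] <-
        res$report$accuracy
    }
  }
  out <- do.call(rbind, lapply(models, function(m) {
    a <- runs$accuracy[runs$model == m]
    data.frame(model = m, mean_accuracy = mean(a),
               sd_accuracy = stats::sd(a), n_seeds = n_seeds)
  }))
  attr(out, "runs") <- runs
  out
}
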
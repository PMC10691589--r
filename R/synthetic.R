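# Synthetic multi-site 9-axis IMU running data with controllable
# fatigue-stage effects. The generator is the package's stand-in for a
# treadmill/track cohort: per-subject periodic gait signals at a fixed
# stride frequency, a per-cycle foot-strike impact transient on the
# vertical accelerometer axis, a per-cycle sagittal swing lobe on the
# gyroscope, and a magnetometer observing a constant world field rotated
# by the simulated segment orientation.

# Per-sensor noise scales (native units at noise_sd = 1).
.NOISE_UNIT <- c(acc = 0.03, gyr = 3.0, mag = 0.005)

# Site gains: amplitude of the base gait signal and attenuation of the
# stage effects. Distal sites carry more impact/swing information.
.SITE_GAIN <- list(
  LL  = list(amp = 1.0, effect = 1.0),
  UL  = list(amp = 0.6, effect = 0.6),
  PEL = list(amp = 0.4, effect = 0.35)
)

#' Subject profile for the synthetic gait generator
#'
#' Describes one simulated runner: stride (full gait cycle) frequency,
#' baseline foot-strike impact amplitude, baseline sagittal swing angular
#' velocity, and a dimensionless sensor-noise level.
#'
#' @param subject_id Character identifier.
#' @param stride_frequency_hz Gait cycles per second; must lie in (0.5, 2.5)
#'   so one full cycle fits inside a 200-sample window at 200 Hz.
#' @param base_impact_g Peak amplitude of the per-cycle vertical impact
#'   transient, in g.
#' @param base_swing_dps Peak sagittal angular velocity of the swing lobe,
#'   in degrees per second.
#' @param noise_sd Dimensionless noise level; 1 maps to 0.03 g, 3 deg/s and
#'   0.005 Gauss additive white noise per channel.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            stride_frequency_hz = 1.4,
                            base_impact_g = 3,
                            base_swing_dps = 200,
                            noise_sd = 1) {
  if (!(stride_frequency_hz > 0.5 && stride_frequency_hz < 2.5))
    stop_invalid("stride_frequency_hz must lie in (0.5, 2.5)")
  if (base_impact_g < 0 || base_swing_dps < 0)
    stop_invalid("base amplitudes must be non-negative")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  structure(list(subject_id = as.character(subject_id),
                 stride_frequency_hz = stride_frequency_hz,
                 base_impact_g = base_impact_g,
                 base_swing_dps = base_swing_dps,
                 noise_sd = noise_sd),
            class = "subject_profile")
}

#' Stage effect descriptor
#'
#' Multiplicative modifiers applied to one fatigue stage, plus the
#' physiological metadata (RPE on the Borg 6-20 scale, heart rate)
#' sampled for that stage.
#'
#' @param stage One of `"Pre"`, `"Mid"`, `"Post"`.
#' @param impact_scale,swing_scale,variability_scale Positive multipliers
#'   on impact amplitude, swing amplitude and noise level.
#' @param orientation_drift_deg Additional mean forward-lean (pitch) in
#'   degrees acquired at the start of the stage.
#' @param rpe_mean,rpe_sd,hr_mean,hr_sd Stage metadata distribution;
#'   defaults follow the cohort's observed per-stage means/SDs
#'   (RPE 6.6/11.9/15.2, HR 163.2/171.8/178.0).
#' @return An object of class `stage_effect`.
#' @export
stage_effect <- function(stage,
                         impact_scale = 1,
                         swing_scale = 1,
                         orientation_drift_deg = 0,
                         variability_scale = 1,
                         rpe_mean = NULL, rpe_sd = NULL,
                         hr_mean = NULL, hr_sd = NULL) {
  stage <- match.arg(stage, STAGES)
  check_positive(impact_scale, "impact_scale")
  check_positive(swing_scale, "swing_scale")
  check_positive(variability_scale, "variability_scale")
  meta <- list(Pre  = c(6.6, 0.8, 163.2, 4.9),
               Mid  = c(11.9, 1.1, 171.8, 5.0),
               Post = c(15.2, 1.5, 178.0, 4.8))[[stage]]
  structure(list(stage = stage,
                 impact_scale = impact_scale,
                 swing_scale = swing_scale,
                 orientation_drift_deg = orientation_drift_deg,
                 variability_scale = variability_scale,
                 rpe_mean = if (is.null(rpe_mean)) meta[1] else rpe_mean,
                 rpe_sd   = if (is.null(rpe_sd))   meta[2] else rpe_sd,
                 hr_mean  = if (is.null(hr_mean))  meta[3] else hr_mean,
                 hr_sd    = if (is.null(hr_sd))    meta[4] else hr_sd),
            class = "stage_effect")
}

#' Default Pre/Mid/Post stage effects
#'
#' Fatigued running is simulated as reduced distal impact loading
#' (impact x0.90 then x0.80), increased limb swing (x1.15 then x1.30),
#' a growing forward-lean drift (0/3/6 degrees) and higher cycle-to-cycle
#' variability (x1.0/x1.1/x1.2). The directions follow the impact-
#' attenuation interpretation of fatigued gait; magnitudes are generator
#' conventions, configurable per effect.
#'
#' @return A list of three `stage_effect` objects (Pre, Mid, Post).
#' @export
default_stage_effects <- function() {
  list(stage_effect("Pre"),
       stage_effect("Mid", impact_scale = 0.90, swing_scale = 1.15,
                    orientation_drift_deg = 3, variability_scale = 1.1),
       stage_effect("Post", impact_scale = 0.80, swing_scale = 1.30,
                    orientation_drift_deg = 6, variability_scale = 1.2))
}

# Gaussian lobe on circular phase in [0, 1).
wrapped_gauss <- function(phase, mu, sd) {
  d <- ((phase - mu + 0.5) %% 1) - 0.5
  exp(-d^2 / (2 * sd^2))
}

# Sagittal swing-rate waveform with zero mean over a cycle: a positive
# swing lobe balanced by a broader counter-rotation lobe so the pitch
# excursion stays bounded and periodic.
swing_wave <- function(phase) {
  wrapped_gauss(phase, 0.30, 0.08) -
    (0.08 / 0.12) * wrapped_gauss(phase, 0.75, 0.12)
}

#' Generate one synthetic IMU recording
#'
#' Simulates a continuous 9-axis recording (accelerometer in g, gyroscope
#' in deg/s, magnetometer in Gauss) at `fs_hz` for one sensor site, as a
#' sequence of fatigue-stage segments. The true segment orientation is
#' obtained by integrating the noise-free body angular rates and is kept
#' on the returned object (`$euler_deg`) as ground truth for orientation-
#' estimation checks.
#'
#' @param profile A [subject_profile()].
#' @param effects Ordered list of [stage_effect()]s, one per stage segment.
#' @param stage_durations_s Positive durations (seconds), one per effect.
#' @param site Sensor site: `"LL"` (shank), `"UL"` (thigh) or `"PEL"` (pelvis).
#' @param seed Integer seed; identical arguments reproduce the recording
#'   exactly.
#' @param fs_hz Sampling frequency, default 200.
#' @return An object of class `imu_recording` with fields `acc`, `gyr`,
#'   `mag` (T x 3 matrices), `stage_labels` (factor), `euler_deg`
#'   (ground-truth roll/pitch/yaw), `fs_hz`, `site`, `subject_id`,
#'   `stage_meta` (per-stage RPE/HR draws).
#' @export
generate_recording <- function(profile, effects, stage_durations_s, site,
                               seed, fs_hz = 200) {
  stopifnot(inherits(profile, "subject_profile"))
  if (length(effects) != length(stage_durations_s))
    stop_invalid("effects and stage_durations_s must have equal length")
  check_positive(stage_durations_s, "stage durations")
  check_positive(fs_hz, "fs_hz")
  site <- check_site(site)
  gain <- .SITE_GAIN[[site]]

  n_per <- as.integer(round(stage_durations_s * fs_hz))
  T_len <- sum(n_per)
  stage_names <- vapply(effects, function(e) e$stage, character(1))
  stage_labels <- as_stage_factor(rep(stage_names, n_per))
  seg_id <- rep(seq_along(effects), n_per)

  # site-attenuated per-sample effect tracks
  att <- function(x) 1 + gain$effect * (x - 1)
  imp_t <- att(vapply(effects, function(e) e$impact_scale, 1))[seg_id]
  swg_t <- att(vapply(effects, function(e) e$swing_scale, 1))[seg_id]
  var_t <- att(vapply(effects, function(e) e$variability_scale, 1))[seg_id]

  tt <- (seq_len(T_len) - 1) / fs_hz
  phase <- (tt * profile$stride_frequency_hz) %% 1

  A_sw  <- profile$base_swing_dps * gain$amp * swg_t
  A_imp <- profile$base_impact_g  * gain$amp * imp_t

  # body angular rates (deg/s), noise-free
  gy <- A_sw * swing_wave(phase)
  gx <- 0.15 * A_sw * sin(2 * pi * phase)
  gz <- 0.10 * A_sw * cos(2 * pi * phase)

  # forward-lean drift: a 1-s raised-cosine pitch-rate pulse at each
  # stage onset carrying the drift increment for that stage
  drift <- gain$effect *
    vapply(effects, function(e) e$orientation_drift_deg, 1)
  seg_start <- cumsum(c(0L, n_per[-length(n_per)])) + 1L
  prev <- 0
  for (k in seq_along(effects)) {
    delta <- drift[k] - prev
    prev <- drift[k]
    if (abs(delta) < 1e-12) next
    Td <- min(1, stage_durations_s[k])
    np <- max(2L, as.integer(round(Td * fs_hz)))
    idx <- seg_start[k] + seq_len(np) - 1L
    tau <- (seq_len(np) - 1) / fs_hz
    gy[idx] <- gy[idx] + delta * (1 - cos(2 * pi * tau / Td)) / Td
  }

  # integrate true body rates -> orientation ground truth
  dt <- 1 / fs_hz
  q <- quat_identity()
  euler <- matrix(0, T_len, 3)
  grav_b <- matrix(0, T_len, 3)
  mag_b <- matrix(0, T_len, 3)
  m_world <- c(0.35, 0, -0.25)
  d2r <- pi / 180
  for (i in seq_len(T_len)) {
    R <- quat_to_matrix(q)
    euler[i, ] <- matrix_to_euler_deg(R)
    grav_b[i, ] <- R[3, ]            # t(R) %*% e3
    mag_b[i, ] <- crossprod(R, m_world)
    q <- quat_normalize(quat_multiply(
      q, quat_from_rotvec(c(gx[i], gy[i], gz[i]) * d2r * dt)))
  }

  # accelerometer: gravity in body frame + impact/bobbing, all scaled by
  # the impact amplitude so the zero-amplitude limit is pure gravity
  acc <- grav_b
  acc[, 3] <- acc[, 3] + A_imp * wrapped_gauss(phase, 0.05, 0.03) +
    0.15 * A_imp * sin(4 * pi * phase)
  acc[, 1] <- acc[, 1] + 0.10 * A_imp * sin(2 * pi * phase)
  acc[, 2] <- acc[, 2] + 0.08 * A_imp * sin(2 * pi * phase + 1)

  gyr <- cbind(gx, gy, gz, deparse.level = 0)
  mag <- mag_b

  rec <- with_seed(seed, {
    ns <- profile$noise_sd * var_t
    if (profile$noise_sd > 0) {
      acc <- acc + matrix(stats::rnorm(3 * T_len), T_len) * (.NOISE_UNIT["acc"] * ns)
      gyr <- gyr + matrix(stats::rnorm(3 * T_len), T_len) * (.NOISE_UNIT["gyr"] * ns)
      mag <- mag + matrix(stats::rnorm(3 * T_len), T_len) * (.NOISE_UNIT["mag"] * ns)
    }
    meta <- data.frame(
      stage = stage_names,
      rpe = vapply(effects, function(e)
        stats::rnorm(1, e$rpe_mean, e$rpe_sd), 1),
      hr = vapply(effects, function(e)
        stats::rnorm(1, e$hr_mean, e$hr_sd), 1))
    list(acc = acc, gyr = gyr, mag = mag, meta = meta)
  })

  # instrument ranges
  rec$acc[] <- pmin(pmax(rec$acc, -16), 16)
  rec$gyr[] <- pmin(pmax(rec$gyr, -500), 500)

  structure(list(subject_id = profile$subject_id,
                 site = site,
                 fs_hz = fs_hz,
                 acc = rec$acc, gyr = rec$gyr, mag = rec$mag,
                 stage_labels = stage_labels,
                 euler_deg = euler,
                 stage_meta = rec$meta,
                 profile = profile),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s, site %s, %d samples @ %g Hz\n",
              x$subject_id, x$site, nrow(x$acc), x$fs_hz))
  print(table(x$stage_labels))
  invisible(x)
}

#' Generate a synthetic cohort of recordings
#'
#' Draws per-subject gait profiles from the configured distributions
#' (stride frequency N(1.4, 0.1) Hz, impact N(3, 0.5) g, swing
#' N(200, 30) deg/s, truncated to valid ranges) and simulates one
#' recording per subject and site. Sub-seeds are derived deterministically
#' from `seed`, so the same call reproduces the cohort exactly.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param sites Character vector of sites from `"LL"`, `"UL"`, `"PEL"`.
#' @param seed Integer master seed.
#' @param stage_durations_s Durations of the Pre/Mid/Post segments.
#' @param effects Stage effects; default [default_stage_effects()].
#' @param noise_sd Noise level given to every subject profile.
#' @return A list of `imu_recording`s of length `n_subjects * length(sites)`.
#' @export
generate_cohort <- function(n_subjects, sites = "LL", seed = 1,
                            stage_durations_s = c(20, 20, 20),
                            effects = default_stage_effects(),
                            noise_sd = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop_invalid("n_subjects must be >= 1")
  if (length(sites) == 0L) stop_invalid("sites must not be empty")
  sites <- vapply(sites, check_site, character(1), USE.NAMES = FALSE)
  recs <- vector("list", n_subjects * length(sites))
  k <- 0L
  for (i in seq_len(n_subjects)) {
    prof <- with_seed(derive_seed(seed, i), {
      subject_profile(
        subject_id = sprintf("S%02d", i),
        stride_frequency_hz = min(2.2, max(0.8, stats::rnorm(1, 1.4, 0.1))),
        base_impact_g = max(1.5, stats::rnorm(1, 3, 0.5)),
        base_swing_dps = max(100, stats::rnorm(1, 200, 30)),
        noise_sd = noise_sd)
    })
    for (s in seq_along(sites)) {
      k <- k + 1L
      recs[[k]] <- generate_recording(
        prof, effects, stage_durations_s, sites[s],
        seed = derive_seed(seed, i, s))
    }
  }
  recs
}

#' Write a recording to CSV
#'
#' Columns: `time_s, ax, ay, az, gx, gy, gz, mx, my, mz, stage`.
#'
#' @param rec An `imu_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(
    time_s = (seq_len(nrow(rec$acc)) - 1) / rec$fs_hz,
    ax = rec$acc[, 1], ay = rec$acc[, 2], az = rec$acc[, 3],
    gx = rec$gyr[, 1], gy = rec$gyr[, 2], gz = rec$gyr[, 3],
    mx = rec$mag[, 1], my = rec$mag[, 2], mz = rec$mag[, 3],
    stage = as.character(rec$stage_labels))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording_csv()]
#'
#' @param path CSV file path.
#' @param subject_id,site Optional metadata to attach.
#' @return An `imu_recording` (without generator ground truth).
#' @export
read_recording_csv <- function(path, subject_id = NA_character_,
                               site = "LL") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "ax", "ay", "az", "gx", "gy", "gz",
            "mx", "my", "mz", "stage")
  if (!all(need %in% names(df)))
    stop_invalid("recording CSV must have columns ",
                 paste(need, collapse = ", "))
  fs <- 1 / stats::median(diff(df$time_s))
  structure(list(subject_id = subject_id,
                 site = check_site(site),
                 fs_hz = round(fs, 6),
                 acc = as.matrix(df[, c("ax", "ay", "az")]),
                 gyr = as.matrix(df[, c("gx", "gy", "gz")]),
                 mag = as.matrix(df[, c("mx", "my", "mz")]),
                 stage_labels = as_stage_factor(df$stage),
                 euler_deg = NULL,
                 stage_meta = NULL,
                 profile = NULL),
            class = "imu_recording")
}
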
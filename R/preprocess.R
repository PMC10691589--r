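# Signal conditioning: Butterworth low-pass filtering of accelerometer /
# gyroscope channels and Kalman-fusion 3D orientation estimation from the
# 9-axis stream.

#' Low-pass filter configuration
#'
#' @param order Filter order (default 4).
#' @param cutoff_hz Cut-off frequency in Hz (default 15).
#' @param fs_hz Sampling frequency in Hz (default 200).
#' @param zero_phase If `TRUE`, apply the filter forward and backward
#'   (zero phase, squared magnitude response); default is a single causal
#'   pass, matching real-time use.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(order = 4, cutoff_hz = 15, fs_hz = 200,
                          zero_phase = FALSE) {
  check_positive(order, "order")
  check_positive(cutoff_hz, "cutoff_hz")
  check_positive(fs_hz, "fs_hz")
  check_flag(zero_phase, "zero_phase")
  if (cutoff_hz >= fs_hz / 2)
    stop_invalid("cutoff_hz must be below the Nyquist frequency fs_hz/2")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 fs_hz = fs_hz, zero_phase = zero_phase),
            class = "filter_config")
}

# Impulse-invariant digital realization of the analog Butterworth
# low-pass: partial fractions over the left-half-plane poles, poles
# mapped by z = exp(sT), numerator rescaled to exact unit DC gain. The
# impulse-invariant mapping tracks the analog magnitude
# 1/sqrt(1+(f/fc)^(2n)) across the band, where the bilinear transform
# would over-attenuate near Nyquist through frequency warping.
butter_impinvar <- function(order, cutoff_hz, fs_hz) {
  wc <- 2 * pi * cutoff_hz
  k <- seq_len(order)
  p <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  r <- vapply(k, function(i) wc^order / prod(p[i] - p[-i]), complex(1))
  Ts <- 1 / fs_hz
  pd <- exp(p * Ts)
  a <- c(1)
  for (i in k) a <- c(a, 0) - c(0, pd[i] * a)
  b <- rep(0 + 0i, order)
  for (i in k) {
    num <- c(1)
    for (j in k[-i]) num <- c(num, 0) - c(0, pd[j] * num)
    b[seq_along(num)] <- b[seq_along(num)] + Ts * r[i] * num
  }
  b <- Re(b); a <- Re(a)
  list(b = b * (sum(a) / sum(b)), a = a)
}

#' Butterworth low-pass filter, column-wise
#'
#' Applies an `order`-th order Butterworth low-pass to each column of a
#' multichannel signal. DC gain is exactly 1; the single-pass magnitude
#' response follows the Butterworth prototype
#' `|H(f)| = 1/sqrt(1 + (f/fc)^(2*order))`.
#'
#' @param x Numeric vector or T x C matrix.
#' @param cfg A [filter_config()].
#' @return Filtered signal with the dimensions of `x`.
#' @export
lowpass_filter <- function(x, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  if (nrow(xm) <= 3 * cfg$order)
    stop_invalid("signal too short: need more than 3*order samples")
  co <- butter_impinvar(cfg$order, cfg$cutoff_hz, cfg$fs_hz)
  flt <- signal::Arma(b = co$b, a = co$a)
  run <- function(v) as.numeric(signal::filter(flt, v))
  y <- xm
  for (j in seq_len(ncol(xm))) {
    y[, j] <- if (cfg$zero_phase)
      rev(run(rev(run(xm[, j]))))     # forward-backward, squared |H|
    else
      run(xm[, j])
  }
  if (vec) as.numeric(y) else y
}

#' Orientation estimate from 9-axis data
#'
#' Quaternion error-state Kalman filter: the gyroscope propagates the
#' attitude, the accelerometer corrects roll/pitch through the gravity
#' direction, and the magnetometer corrects yaw through a world field
#' reference taken from the first sample. Accelerometer updates are gated
#' when the measured specific force deviates from 1 g by more than
#' `acc_gate` (impacts are not gravity).
#'
#' @param acc T x 3 accelerometer matrix in g.
#' @param gyr T x 3 gyroscope matrix in deg/s.
#' @param mag T x 3 magnetometer matrix (any consistent unit).
#' @param fs_hz Sampling frequency in Hz.
#' @param gyro_noise_dps Process noise (gyro white noise, deg/s).
#' @param acc_noise Measurement noise SD of the unit gravity vector.
#' @param mag_noise Measurement noise SD of the unit field vector.
#' @param acc_gate Gate half-width on | |acc| - 1 g |, in g: samples
#'   outside the gate do not enter the gravity innovation smoother.
#' @param innovation_tau Time constant (s) of the innovation smoothing;
#'   about one gait cycle.
#' @param init_att_sd_deg Initial attitude uncertainty, degrees.
#' @return An object of class `orientation_series`: list with `euler_deg`
#'   (T x 3 roll/pitch/yaw, degrees, wrapped to \[-180, 180\]) and `fs_hz`.
#' @export
estimate_orientation <- function(acc, gyr, mag, fs_hz = 200,
                                 gyro_noise_dps = 0.3,
                                 acc_noise = 0.25,
                                 mag_noise = 0.4,
                                 acc_gate = 0.5,
                                 innovation_tau = 1,
                                 init_att_sd_deg = 10) {
  acc <- as.matrix(acc); gyr <- as.matrix(gyr); mag <- as.matrix(mag)
  T_len <- nrow(acc)
  if (T_len < 2 || nrow(gyr) != T_len || nrow(mag) != T_len)
    stop_invalid("acc, gyr, mag must share length T >= 2")
  check_positive(fs_hz, "fs_hz")
  anorm <- sqrt(rowSums(acc^2))
  if (all(anorm < 1e-9))
    stop_invalid("degenerate attitude: accelerometer norm is zero")

  dt <- 1 / fs_hz
  d2r <- pi / 180

  # Moving-base coarse alignment: rotate the opening window of
  # accelerometer and magnetometer samples into the frame of sample 1
  # using the integrated gyroscope, then average. Periodic linear
  # accelerations (foot strikes, bobbing) largely cancel over whole gait
  # cycles, leaving the gravity and field directions at the start.
  align_n <- min(T_len, max(2L, as.integer(round(2 * fs_hz))))
  qg <- quat_identity()               # body(t) -> body(1)
  g_sum <- c(0, 0, 0); m_sum <- c(0, 0, 0)
  for (i in seq_len(align_n)) {
    Rg <- quat_to_matrix(qg)
    g_sum <- g_sum + Rg %*% acc[i, ]
    m_sum <- m_sum + Rg %*% mag[i, ]
    qg <- quat_normalize(quat_multiply(qg, quat_from_rotvec(gyr[i, ] * d2r * dt)))
  }
  gn <- sqrt(sum(g_sum^2))
  if (gn < 1e-9)
    stop_invalid("degenerate attitude: accelerometer mean is zero over ",
                 "the alignment window")
  a0 <- g_sum / gn
  roll0 <- atan2(a0[2], a0[3])
  pitch0 <- atan2(-a0[1], sqrt(a0[2]^2 + a0[3]^2))
  R1 <- euler_deg_to_matrix(c(roll0, pitch0, 0) / d2r)  # yaw 0 at start
  q <- rotmat_to_quat(R1)

  # world magnetic reference from the aligned average
  mn0 <- sqrt(sum(m_sum^2))
  if (mn0 > 1e-9) {
    m_world <- as.numeric(R1 %*% (m_sum / mn0))
    use_mag <- TRUE
  } else {
    m_world <- c(1, 0, 0)
    use_mag <- FALSE
  }

  P <- diag(3) * (init_att_sd_deg * d2r)^2
  Qc <- diag(3) * (gyro_noise_dps * d2r)^2 * dt
  Ra <- diag(3) * acc_noise^2
  Rm <- diag(3) * mag_noise^2
  I3 <- diag(3)

  # Corrections use innovations smoothed over roughly a gait cycle:
  # running linear accelerations are periodic, so their contribution to
  # the smoothed gravity innovation averages out while an attitude error
  # does not. Samples far from 1 g (foot strikes) are kept out of the
  # smoother as well.
  lam <- min(1, dt / innovation_tau)
  nu_a <- c(0, 0, 0); nu_m <- c(0, 0, 0)
  euler <- matrix(0, T_len, 3)
  for (i in seq_len(T_len)) {
    if (i > 1) {
      w <- gyr[i - 1, ] * d2r
      q <- quat_normalize(quat_multiply(q, quat_from_rotvec(w * dt)))
      A <- I3 - skew(w * dt)
      P <- A %*% P %*% t(A) + Qc
    }
    Rq <- quat_to_matrix(q)

    # gravity correction
    h <- Rq[3, ]                         # t(Rq) %*% e3
    if (anorm[i] > 1e-9 && abs(anorm[i] - 1) < acc_gate)
      nu_a <- nu_a + lam * ((acc[i, ] / anorm[i] - h) - nu_a)
    H <- skew(h)
    K <- P %*% t(H) %*% solve(H %*% P %*% t(H) + Ra)
    dth <- as.numeric(K %*% nu_a)
    q <- quat_normalize(quat_multiply(q, quat_from_rotvec(dth)))
    P <- (I3 - K %*% H) %*% P
    Rq <- quat_to_matrix(q)

    # magnetic yaw correction
    mn <- sqrt(sum(mag[i, ]^2))
    if (use_mag && mn > 1e-9) {
      h <- as.numeric(crossprod(Rq, m_world))
      nu_m <- nu_m + lam * ((mag[i, ] / mn - h) - nu_m)
      H <- skew(h)
      K <- P %*% t(H) %*% solve(H %*% P %*% t(H) + Rm)
      dth <- as.numeric(K %*% nu_m)
      q <- quat_normalize(quat_multiply(q, quat_from_rotvec(dth)))
      P <- (I3 - K %*% H) %*% P
      Rq <- quat_to_matrix(q)
    }

    euler[i, ] <- matrix_to_euler_deg(Rq)
  }
  structure(list(euler_deg = wrap_deg(euler), fs_hz = fs_hz),
            class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series> %d samples @ %g Hz (roll/pitch/yaw deg)\n",
              nrow(x$euler_deg), x$fs_hz))
  invisible(x)
}

# Rotation matrix (body->world) -> unit quaternion, scalar first.
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  quat_normalize(q)
}
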
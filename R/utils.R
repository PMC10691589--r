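#' @keywords internal
#' @useDynLib runfatigue, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# ---- argument checks ------------------------------------------------------

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0))
    stop_invalid(what, " must be positive and finite")
  invisible(x)
}

check_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_invalid(what, " must be TRUE or FALSE")
  invisible(x)
}

STAGES <- c("Pre", "Mid", "Post")
SITES  <- c("LL", "UL", "PEL")

check_site <- function(site) {
  if (!is.character(site) || length(site) != 1L || !site %in% SITES)
    stop_invalid("unknown sensor site: must be one of ", paste(SITES, collapse = ", "))
  site
}

as_stage_factor <- function(x) factor(as.character(x), levels = STAGES)

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the
# caller's RNG state afterwards so generation never perturbs user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  ix <- c(seed, ...)
  s <- 0
  for (v in ix) s <- (s * 69069 + as.double(v) * 101 + 17) %% 2147483647
  as.integer(s)
}

# ---- quaternion helpers (unit quaternions, scalar-first, body->world) -----

quat_identity <- function() c(1, 0, 0, 0)

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

# Rotation vector (radians, body frame) -> quaternion increment.
quat_from_rotvec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(quat_normalize(c(1, v / 2)))
  c(cos(th / 2), sin(th / 2) * v / th)
}

# Body->world rotation matrix of q.
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

# Intrinsic Z-Y-X (yaw-pitch-roll) Euler angles in degrees from a
# body->world rotation matrix; output order (roll, pitch, yaw).
matrix_to_euler_deg <- function(R) {
  pitch <- asin(pmin(1, pmax(-1, -R[3, 1])))
  roll  <- atan2(R[3, 2], R[3, 3])
  yaw   <- atan2(R[2, 1], R[1, 1])
  c(roll, pitch, yaw) * 180 / pi
}

euler_deg_to_matrix <- function(e) {
  r <- e * pi / 180
  cr <- cos(r[1]); sr <- sin(r[1])
  cp <- cos(r[2]); sp <- sin(r[2])
  cy <- cos(r[3]); sy <- sin(r[3])
  Rz <- matrix(c(cy, -sy, 0, sy, cy, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cp, 0, sp, 0, 1, 0, -sp, 0, cp), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cr, -sr, 0, sr, cr), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

skew <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, byrow = TRUE)
}

wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}
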
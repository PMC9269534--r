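# Per-sensor orientation estimation during movement: exact-exponential gyro
# propagation corrected toward the absolute gravity/field (TRIAD) observation
# by a complementary filter with gyro-bias integral feedback. The corrector
# is gated by the accelerometer norm (linear acceleration contaminates the
# gravity direction) and by the gyro rate, and a zero-rate update estimates
# the gyro bias directly during detected static intervals.

#' Fusion filter parameters
#'
#' Tunable weights of the attitude filter. `accel_trust` and `mag_trust`
#' scale the attitude correction gain; `bias_process` (deg/s^2, the assumed
#' gyro-bias random walk) scales the bias integral gain. Setting both trust
#' weights to zero and `zupt = FALSE` yields pure gyro dead-reckoning.
#'
#' @param gyro_noise Gyro noise density in deg/s/sqrt(Hz) (diagnostic; feeds
#'   the covariance bookkeeping, not the gains).
#' @param accel_trust,mag_trust Dimensionless observation weights (default 1).
#' @param bias_process Gyro-bias random-walk intensity in deg/s^2.
#' @param gate_dev Fractional accelerometer-norm deviation from 1 g at which
#'   down-weighting starts (default 0.10); the weight reaches zero at twice
#'   this value.
#' @param gate_rate Gyro rate (deg/s) at which the correction weight is
#'   halved; suppresses corrections during fast motion, where the gravity
#'   observation is least trustworthy.
#' @param zupt Logical: run the zero-rate gyro-bias update during detected
#'   static intervals (default `TRUE`).
#' @return A list of class `"fusion_params"`.
#' @export
fusion_params <- function(gyro_noise = 0.2, accel_trust = 1, mag_trust = 1,
                          bias_process = 0.01, gate_dev = 0.10,
                          gate_rate = 20, zupt = TRUE) {
  stopifnot(
    gyro_noise >= 0, accel_trust >= 0, mag_trust >= 0, bias_process >= 0,
    gate_dev > 0, gate_rate > 0, is.logical(zupt)
  )
  trust <- (accel_trust + mag_trust) / 2
  out <- list(
    gyro_noise = gyro_noise, accel_trust = accel_trust,
    mag_trust = mag_trust, bias_process = bias_process,
    gate_dev = gate_dev, gate_rate = gate_rate, zupt = zupt,
    # correction gains: attitude (1/s) and bias integral (1/s^2)
    k_att = 0.5 * trust,
    k_bias = 10 * bias_process * trust,
    k_zupt = 2
  )
  class(out) <- "fusion_params"
  out
}

#' Absolute orientation from one gravity/field observation
#'
#' TRIAD-style observation: builds the gravity/field basis from a single
#' (or averaged) accelerometer and magnetometer reading and returns the
#' quaternion rotating the measuring frame onto the anatomical frame. For a
#' segment at the calibration pose this is the identity.
#'
#' @param a Accelerometer 3-vector (m/s^2) in the calibrated segment frame.
#' @param b Magnetometer 3-vector (microtesla), same frame.
#' @return A unit quaternion (segment to anatomical).
#' @export
static_orientation <- function(a, b) {
  Bm <- build_basis(a, b)$B
  matrix_to_quat(reference_basis() %*% t(Bm))
}

#' Advance a quaternion by one gyro increment
#'
#' Exact exponential-map propagation by the body-frame axis-angle increment
#' `w * dt`, then renormalization.
#'
#' @param q Current orientation quaternion.
#' @param w Angular velocity 3-vector in deg/s (body frame).
#' @param dt Time step in seconds, positive.
#' @return The propagated unit quaternion.
#' @export
integrate_gyro <- function(q, w, dt) {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
  quat_multiply(quat(q), quat_from_rotvec(w * dt))
}

#' Fuse a calibrated sensor stream into an orientation track
#'
#' Runs the attitude filter over a uniformly sampled, calibrated stream:
#' gyro propagation by [integrate_gyro()], corrected toward the
#' [static_orientation()] observation with gain `k_att * weight`, where the
#' weight combines the accelerometer-norm gate and the gyro-rate gate; the
#' gyro-bias state receives integral feedback plus a direct zero-rate update
#' when the stream is detected static for at least `0.3` s. Deterministic
#' given the stream and parameters, and invariant to a uniform time shift.
#'
#' @param stream A calibrated `imu_stream` (see [apply_calibration()]), or a
#'   raw one if `calib` is supplied.
#' @param calib Optional `"elbow_calibration"` applied before filtering.
#' @param params A [fusion_params()] list.
#' @param sensor `"arm"` or `"forearm"`, used only when `calib` is given.
#' @return A tibble of class `"orientation_track"` with columns `t`, `qw`,
#'   `qx`, `qy`, `qz`, plus the per-sample correction `weight` and the final
#'   bias estimate in attribute `bias` (deg/s).
#' @export
fuse_stream <- function(stream, calib = NULL, params = fusion_params(),
                        sensor = NULL) {
  if (!is.null(calib)) {
    stream <- apply_calibration(stream, calib, sensor = sensor)
  }
  n <- nrow(stream)
  if (n < 1L) {
    stop("Cannot fuse an empty stream.", call. = FALSE)
  }
  t <- stream$t
  if (n > 1L) {
    dts <- diff(t)
    dt <- stats::median(dts)
    if (any(abs(dts - dt) > 0.1 * dt)) {
      stop("Irregular sampling: timestamp jitter exceeds 10 % of the ",
           "median period.", call. = FALSE)
    }
  } else {
    dt <- 0
  }
  A <- .stream_mat(stream, c("ax", "ay", "az"))
  G <- .stream_mat(stream, c("gx", "gy", "gz"))
  M <- .stream_mat(stream, c("mx", "my", "mz"))

  # initial attitude from the first ~0.5 s (static in normal protocols)
  n0 <- max(1L, min(n, as.integer(round(0.5 / max(dt, 1e-6)))))
  q <- tryCatch(
    static_orientation(colMeans(A[seq_len(n0), , drop = FALSE]),
                       colMeans(M[seq_len(n0), , drop = FALSE])),
    error = function(e) quat(1, 0, 0, 0)
  )
  bias <- c(0, 0, 0)
  # diagonal error covariance bookkeeping (attitude deg^2, bias (deg/s)^2)
  p_att <- rep(1, 3)
  p_bias <- rep(0.25, 3)

  Q <- matrix(NA_real_, n, 4)
  wts <- numeric(n)
  static_run <- 0L
  steady_run <- 0L
  rate <- if (dt > 0) 1 / dt else 0
  min_static <- as.integer(ceiling(0.3 * rate))
  P0 <- reference_basis()

  for (i in seq_len(n)) {
    if (i > 1L) {
      q <- integrate_gyro(q, G[i - 1L, ] - bias, dt)
      p_att <- p_att + (params$gyro_noise^2 * dt + p_bias * dt^2)
      p_bias <- p_bias + params$bias_process^2 * dt
    }
    a <- A[i, ]
    m <- M[i, ]
    dev <- abs(sqrt(sum(a^2)) - GRAVITY) / GRAVITY
    w_norm <- if (dev <= params$gate_dev) 1
              else max(0, 1 - (dev - params$gate_dev) / params$gate_dev)
    rate_now <- sqrt(sum((G[i, ] - bias)^2))
    # steep gate: the gravity observation is unusable during fast motion
    # (linear acceleration perpendicular to gravity passes the norm test)
    w_rate <- 1 / (1 + (rate_now / params$gate_rate)^4)
    wt <- w_norm * w_rate
    # the quasi-static condition must hold for a sustained window before a
    # correction is applied: movement turnarounds also show low gyro rate,
    # but only briefly, and exactly there the tangential acceleration peaks
    steady_run <- if (w_norm > 0.5 && rate_now < params$gate_rate) {
      steady_run + 1L
    } else {
      0L
    }
    wt <- wt * (steady_run >= min_static)
    if (dt > 0 && wt > 0 && params$k_att > 0) {
      obs <- tryCatch(matrix_to_quat(P0 %*% t(build_basis(a, m)$B)),
                      error = function(e) NULL)
      if (!is.null(obs)) {
        # error rotation in the body frame; canonical form keeps it <= 180
        err <- quat_to_rotvec(quat_multiply(quat_conjugate(q), obs))
        q <- quat_multiply(q, quat_from_rotvec(params$k_att * wt * dt * err))
        # integral (bias) feedback only under near-static confidence and in
        # the small-error regime, so transient observation errors at motion
        # onset cannot pump the bias state
        if (wt > 0.5 && sqrt(sum(err^2)) < 1) {
          bias <- bias - params$k_bias * wt * dt * err
        }
        p_att <- p_att * (1 - min(1, params$k_att * wt * dt))
      }
    }
    if (dt > 0 && params$zupt) {
      # static means: low accel deviation, low gyro rate, and no rate jump
      # from the previous sample (movement onset shows low rate for one
      # sample before the gate can react)
      jump <- if (i > 1L) sqrt(sum((G[i, ] - G[i - 1L, ])^2)) else 0
      is_static <- dev < 0.03 && sqrt(sum((G[i, ] - bias)^2)) < 3 && jump < 1
      static_run <- if (is_static) static_run + 1L else 0L
      if (static_run >= min_static) {
        bias <- bias + params$k_zupt * dt * (G[i, ] - bias)
        p_bias <- p_bias * (1 - min(1, params$k_zupt * dt))
      }
    }
    Q[i, ] <- q
    wts[i] <- wt
  }

  out <- tibble::tibble(t = t, qw = Q[, 1], qx = Q[, 2], qy = Q[, 3],
                        qz = Q[, 4], weight = wts)
  attr(out, "bias") <- bias
  attr(out, "rate") <- attr(stream, "rate")
  attr(out, "segment") <- attr(stream, "sensor_id")
  class(out) <- c("orientation_track", class(out))
  out
}

#' Orientation track from ground-truth quaternions
#'
#' Packs a matrix of quaternion rows into the track container used by the
#' kinematics layer; mainly for comparing the pipeline against simulator
#' ground truth while bypassing fusion.
#'
#' @param t Time vector (s).
#' @param q An n-by-4 matrix of unit quaternion rows (w, x, y, z).
#' @return An `"orientation_track"` tibble.
#' @export
orientation_track <- function(t, q) {
  q <- as.matrix(q)
  stopifnot(length(t) == nrow(q), ncol(q) == 4L)
  out <- tibble::tibble(t = as.numeric(t), qw = q[, 1], qx = q[, 2],
                        qy = q[, 3], qz = q[, 4], weight = NA_real_)
  class(out) <- c("orientation_track", class(out))
  out
}
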
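# Static-pose sensor-to-segment calibration. A worn sensor is related to its
# body segment by a configured mounting rotation R_i; residual misalignment
# is estimated from a short static capture in the calibration pose (upright,
# arms at the sides, palms facing the body) by building an orthonormal basis
# from the mean gravity reaction and magnetic field, and comparing it with
# the forearm sensor, which is taken as the reference frame (M_2 = I).

GRAVITY <- 9.81 # m/s^2

#' Anatomical-frame reference vectors
#'
#' The anatomical frame is right-handed with X vertical pointing along
#' gravity (down), Y anteroposterior (forward) and Z mediolateral (right).
#' `anatomical_gravity()` returns the accelerometer reading at rest (the
#' reaction force, +1 g opposing gravity, hence along -X);
#' `anatomical_field()` the earth magnetic field with its horizontal
#' component along +Y (forward = magnetic north) and vertical component
#' along +X (down).
#'
#' @param magnitude Field magnitude in microtesla.
#' @param dip Magnetic dip (inclination) in degrees below horizontal.
#' @return A numeric 3-vector in anatomical coordinates.
#' @export
anatomical_gravity <- function() {
  c(-GRAVITY, 0, 0)
}

#' @rdname anatomical_gravity
#' @export
anatomical_field <- function(magnitude = 48, dip = 35) {
  magnitude * c(sin(dip * pi / 180), cos(dip * pi / 180), 0)
}

#' Basis produced by a perfectly aligned sensor
#'
#' The constant matrix that [build_basis()] returns for a sensor whose axes
#' coincide with the anatomical frame: the documented signed permutation
#' linking the gravity/field basis vectors (v1 along the measured gravity
#' reaction) to the anatomical X, Y, Z axes. It depends only on the sign
#' conventions, not on the field dip.
#'
#' @return A 3x3 proper rotation matrix.
#' @export
reference_basis <- function() {
  build_basis(anatomical_gravity(), anatomical_field())$B
}

#' Build a nine-channel sensor stream tibble
#'
#' One row per sample: time `t` (s), sample index `k`, accelerometer
#' `ax, ay, az` (m/s^2), gyroscope `gx, gy, gz` (deg/s) and magnetometer
#' `mx, my, mz` (microtesla). The sampling rate and sensor id (1 = arm,
#' 2 = forearm) travel as attributes.
#'
#' @param t Time in seconds, strictly increasing.
#' @param accel,gyro,mag n-by-3 matrices (or data frames) of sensor readings.
#' @param rate Sampling rate in Hz; one of 30, 60, 120.
#' @param sensor_id Integer sensor id, 1 (arm) or 2 (forearm).
#' @return A tibble of class `"imu_stream"`.
#' @export
imu_stream <- function(t, accel, gyro, mag, rate = 60, sensor_id = NA_integer_) {
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  mag <- as.matrix(mag)
  n <- length(t)
  stopifnot(
    nrow(accel) == n, nrow(gyro) == n, nrow(mag) == n,
    ncol(accel) == 3L, ncol(gyro) == 3L, ncol(mag) == 3L
  )
  if (!all(is.finite(t)) || !all(is.finite(accel)) || !all(is.finite(gyro)) ||
      !all(is.finite(mag))) {
    stop("Sensor samples must be finite.", call. = FALSE)
  }
  if (n > 1L && any(diff(t) <= 0)) {
    stop("Sample times must be strictly increasing.", call. = FALSE)
  }
  out <- tibble::tibble(
    t = as.numeric(t), k = seq_len(n) - 1L,
    ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
    mx = mag[, 1], my = mag[, 2], mz = mag[, 3]
  )
  attr(out, "rate") <- rate
  attr(out, "sensor_id") <- sensor_id
  class(out) <- c("imu_stream", class(out))
  out
}

.stream_mat <- function(stream, cols) {
  unname(as.matrix(stream[, cols]))
}

#' Rotate the vector channels of a sensor stream
#'
#' Pre-multiplies the acceleration, angular-velocity and magnetic-field
#' vectors of every sample by `M %*% R`. With `M` equal to the identity this
#' expresses raw sensor readings in the (approximate) anatomical frame via
#' the mounting rotation alone; with a calibrated `M` it additionally removes
#' the residual sensor-to-segment misalignment. Times, indices and vector
#' norms are unchanged.
#'
#' @param stream An `imu_stream` tibble (or any tibble with the nine sensor
#'   columns).
#' @param M Calibration rotation matrix (default identity).
#' @param R Mounting rotation matrix (default identity).
#' @return The transformed stream, same shape and attributes.
#' @export
transform_stream <- function(stream, M = diag(3), R = diag(3)) {
  stopifnot(is_rotation_matrix(M), is_rotation_matrix(R))
  MR <- M %*% R
  out <- stream
  for (cols in list(c("ax", "ay", "az"), c("gx", "gy", "gz"),
                    c("mx", "my", "mz"))) {
    out[, cols] <- .stream_mat(stream, cols) %*% t(MR)
  }
  out
}

#' Mean acceleration and magnetic field over a static capture
#'
#' Component-wise arithmetic means of the frame-transformed accelerometer
#' and magnetometer channels over all samples of a static capture.
#'
#' @param capture An `imu_stream` tibble taken in the calibration pose.
#' @param R Mounting rotation applied before averaging (default identity,
#'   i.e. the capture is already frame-transformed).
#' @return A list with 3-vectors `mean_a` (m/s^2) and `mean_b` (microtesla).
#' @export
mean_vectors <- function(capture, R = diag(3)) {
  if (nrow(capture) < 1L) {
    stop("Static capture is empty.", call. = FALSE)
  }
  capture <- transform_stream(capture, R = R)
  list(
    mean_a = colMeans(.stream_mat(capture, c("ax", "ay", "az"))),
    mean_b = colMeans(.stream_mat(capture, c("mx", "my", "mz")))
  )
}

#' Orthonormal basis from mean gravity and field vectors
#'
#' The first basis vector points along the mean acceleration, the second is
#' the normalized cross product of the first with the mean magnetic field,
#' and the third completes the right-handed set. The columns of `B` are
#' these vectors, so `B` is a proper rotation.
#'
#' @param mean_a Mean acceleration 3-vector (m/s^2).
#' @param mean_b Mean magnetic field 3-vector (microtesla).
#' @param eps Degeneracy threshold on the vector norms.
#' @return A list with unit vectors `v1`, `v2`, `v3` and the 3x3 matrix `B`.
#' @export
build_basis <- function(mean_a, mean_b, eps = 1e-6) {
  stopifnot(length(mean_a) == 3L, length(mean_b) == 3L)
  na <- sqrt(sum(mean_a^2))
  if (!is.finite(na) || na <= eps) {
    stop("Degenerate gravity: mean acceleration is (near) zero; ",
         "the static pose is unusable.", call. = FALSE)
  }
  v1 <- mean_a / na
  cr <- .cross3(v1, mean_b)
  ncr <- sqrt(sum(cr^2))
  if (!is.finite(ncr) || ncr <= eps) {
    stop("Degenerate field: mean magnetic field is (near) parallel to the ",
         "mean acceleration; the static pose is unusable.", call. = FALSE)
  }
  v2 <- cr / ncr
  v3 <- .cross3(v1, v2)
  list(v1 = v1, v2 = v2, v3 = v3, B = cbind(v1, v2, v3, deparse.level = 0))
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Calibration matrix relating a sensor basis to the reference basis
#'
#' The forearm sensor (id 2) is the reference frame and gets the identity
#' exactly. For the arm sensor the matrix maps its frame-transformed
#' measurements onto the reference: `M = B_2 %*% t(B_i)` (the inverse of an
#' orthonormal basis is its transpose). The product order is fixed so that
#' `M %*% R` carries the measured static vectors onto the reference
#' gravity/field directions.
#'
#' @param basis_i Basis of the sensor being calibrated (from [build_basis()]).
#' @param basis_2 Basis of the reference (forearm) sensor.
#' @param sensor_id 1 (arm) or 2 (forearm).
#' @return A 3x3 proper rotation matrix; identity for `sensor_id = 2`.
#' @export
calibration_matrix <- function(basis_i, basis_2, sensor_id) {
  if (identical(as.integer(sensor_id), 2L)) {
    return(diag(3))
  }
  basis_2$B %*% t(basis_i$B)
}

#' Configured mounting rotation of a worn sensor
#'
#' The donning-time rotation placing a sensor's axes relative to its
#' segment: a rotation by the odd-numbered delta angle about X followed by
#' an intrinsic rotation by the even-numbered delta about the rotated Y
#' axis, `R = Rx(d_odd) %*% Ry(d_even)`. The arm sensor's first angle
#' defaults to the printed 270 degrees; the remaining deltas default to 0
#' and are configuration inputs.
#'
#' @param sensor_id 1 (arm) or 2 (forearm).
#' @param delta Length-2 numeric: the (odd, even) delta angles in degrees.
#'   Defaults to `c(270, 0)` for sensor 1 and `c(0, 0)` for sensor 2.
#' @return A list of class `"mounting"` with fields `sensor_id`, `delta`
#'   and the rotation matrix `R`.
#' @export
mounting_rotation <- function(sensor_id, delta = NULL) {
  sensor_id <- as.integer(sensor_id)
  stopifnot(sensor_id %in% c(1L, 2L))
  if (is.null(delta)) {
    delta <- if (sensor_id == 1L) c(270, 0) else c(0, 0)
  }
  stopifnot(length(delta) == 2L, all(is.finite(delta)))
  out <- list(
    sensor_id = sensor_id,
    delta = wrap_deg(delta),
    R = compose_intrinsic(rot_axis("X", delta[1]), rot_axis("Y", delta[2]))
  )
  class(out) <- "mounting"
  out
}

#' Default mounting pair for the two-sensor upper-limb setup
#'
#' @param delta1,delta2 Arm-sensor delta angles (degrees).
#' @param delta3,delta4 Forearm-sensor delta angles (degrees).
#' @return A list with elements `arm` and `forearm`, each a `"mounting"`.
#' @export
default_mounts <- function(delta1 = 270, delta2 = 0, delta3 = 0, delta4 = 0) {
  list(
    arm = mounting_rotation(1L, c(delta1, delta2)),
    forearm = mounting_rotation(2L, c(delta3, delta4))
  )
}

#' Perturb a mounting rotation by a known misalignment
#'
#' Composes an extra rotation onto the mounting (sensor side), emulating a
#' sensor strapped on slightly off its nominal orientation. Used to exercise
#' calibration recovery.
#'
#' @param mount A `"mounting"` object.
#' @param rotvec Rotation vector of the misalignment in degrees, or `NULL`
#'   to draw a random axis with angle `angle`.
#' @param angle Misalignment angle in degrees when `rotvec` is `NULL`.
#' @return The mounting with `R` replaced by `R %*% E` and the perturbation
#'   stored in field `perturbation`.
#' @export
perturb_mounting <- function(mount, rotvec = NULL, angle = 10) {
  if (is.null(rotvec)) {
    ax <- stats::rnorm(3)
    rotvec <- ax / sqrt(sum(ax^2)) * angle
  }
  E <- quat_to_matrix(quat_from_rotvec(rotvec))
  mount$R <- mount$R %*% E
  mount$perturbation <- E
  mount
}

#' Static-pose calibration of the two-sensor setup
#'
#' Runs the full static-pose pipeline for both sensors: frame transform by
#' the configured mounting rotations, static means, orthonormal bases, and
#' calibration matrices with the forearm as reference (`M_2 = I`).
#'
#' @param static_arm,static_forearm `imu_stream` captures taken in the
#'   calibration pose at the same rate.
#' @param mounts Mounting pair as returned by [default_mounts()].
#' @return An object of class `"elbow_calibration"`: per-sensor calibration
#'   matrices `M1`, `M2`, mountings, mean vectors and bases.
#' @examples
#' s <- simulate_session(protocol = NULL, t_cal = 1, noise = noise_model("none"))
#' cal <- calibrate(s$arm, s$forearm)
#' max(abs(cal$M1 - diag(3))) # perfect mounting -> identity
#' @export
calibrate <- function(static_arm, static_forearm, mounts = default_mounts()) {
  res <- purrr::imap(
    list(arm = static_arm, forearm = static_forearm),
    function(capture, which) {
      mount <- mounts[[which]]
      tryCatch({
        mv <- mean_vectors(capture, R = mount$R)
        basis <- build_basis(mv$mean_a, mv$mean_b)
        list(mount = mount, mean = mv, basis = basis)
      }, error = function(e) {
        stop("Calibration failed for the ", which, " sensor (id ",
             mount$sensor_id, "): ", conditionMessage(e), call. = FALSE)
      })
    }
  )
  out <- list(
    M1 = calibration_matrix(res$arm$basis, res$forearm$basis, 1L),
    M2 = calibration_matrix(res$forearm$basis, res$forearm$basis, 2L),
    mounts = list(arm = res$arm$mount, forearm = res$forearm$mount),
    mean_a = list(arm = res$arm$mean$mean_a, forearm = res$forearm$mean$mean_a),
    mean_b = list(arm = res$arm$mean$mean_b, forearm = res$forearm$mean$mean_b),
    basis = list(arm = res$arm$basis, forearm = res$forearm$basis),
    n = c(arm = nrow(static_arm), forearm = nrow(static_forearm))
  )
  class(out) <- "elbow_calibration"
  out
}

#' @export
print.elbow_calibration <- function(x, ...) {
  ang <- sqrt(sum(quat_to_rotvec(matrix_to_quat(x$M1))^2))
  cat("<elbow_calibration>\n")
  cat(sprintf("  arm residual correction: %.3f deg (M1)\n", ang))
  cat("  forearm: reference frame (M2 = I)\n")
  cat(sprintf("  static samples: arm %d, forearm %d\n", x$n[["arm"]],
              x$n[["forearm"]]))
  invisible(x)
}

#' Apply a calibration to a raw sensor stream
#'
#' Convenience wrapper around [transform_stream()] picking the right
#' `M_i %*% R_i` for the stream's sensor.
#'
#' @param stream Raw `imu_stream`.
#' @param calib An `"elbow_calibration"`.
#' @param sensor One of `"arm"`, `"forearm"`; defaults to the stream's
#'   `sensor_id` attribute.
#' @return The calibrated stream in the anatomical segment frame.
#' @export
apply_calibration <- function(stream, calib, sensor = NULL) {
  if (is.null(sensor)) {
    sensor <- c("arm", "forearm")[attr(stream, "sensor_id")]
  }
  sensor <- match.arg(sensor, c("arm", "forearm"))
  M <- if (sensor == "arm") calib$M1 else calib$M2
  transform_stream(stream, M = M, R = calib$mounts[[sensor]]$R)
}
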
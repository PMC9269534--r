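# 3-D rotation algebra: elemental axis rotations, intrinsic composition,
# quaternion / Euler / matrix conversions. Hamilton convention, scalar-first
# quaternions, canonical sign w >= 0. Angles are degrees at every public
# boundary; radians only inside a function body.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Wrap angles into (-180, 180]
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles reduced modulo 360 into the half-open interval (-180, 180].
#' @examples
#' wrap_deg(c(270, -270, 180, 540))
#' @export
wrap_deg <- function(x) {
  out <- (x + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

#' Elemental rotation matrix about a coordinate axis
#'
#' Right-handed rotation about the X, Y or Z axis of the current frame.
#' The Z form is the sagittal-plane (flexion-extension) matrix and the X form
#' the transverse-plane (pronation-supination) matrix used in joint-angle
#' extraction.
#'
#' @param axis One of `"X"`, `"Y"`, `"Z"` (case-insensitive).
#' @param angle Rotation angle in degrees; must be finite.
#' @return A 3x3 proper rotation matrix.
#' @examples
#' rot_axis("Z", 90)
#' rot_axis("X", 90) %*% c(0, 1, 0) # -> (0, 0, 1)
#' @export
rot_axis <- function(axis, angle) {
  if (!is.numeric(angle) || length(angle) != 1L || !is.finite(angle)) {
    stop("`angle` must be a single finite number (degrees).", call. = FALSE)
  }
  axis <- toupper(as.character(axis))
  if (!axis %in% c("X", "Y", "Z")) {
    stop("`axis` must be one of \"X\", \"Y\", \"Z\".", call. = FALSE)
  }
  a <- angle * DEG2RAD
  c_ <- cos(a)
  s_ <- sin(a)
  switch(axis,
    X = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    Y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    Z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  )
}

#' Compose two rotations intrinsically
#'
#' Applies `second` about the axes already rotated by `first`, i.e. the
#' ordinary matrix product `first %*% second`. This is the composition rule
#' for mounting rotations ("rotation about the actual Y axis" after a first
#' rotation about X).
#'
#' @param first,second 3x3 rotation matrices.
#' @return The composed 3x3 rotation matrix.
#' @examples
#' compose_intrinsic(rot_axis("X", 270), rot_axis("Y", 0))
#' @export
compose_intrinsic <- function(first, second) {
  stopifnot(is_rotation_matrix(first), is_rotation_matrix(second))
  first %*% second
}

#' Test whether a matrix is a proper rotation
#'
#' @param r Object to test.
#' @param tol Orthonormality / determinant tolerance.
#' @return `TRUE` if `r` is a 3x3 orthonormal matrix with determinant +1.
#' @export
is_rotation_matrix <- function(r, tol = 1e-9) {
  is.matrix(r) && all(dim(r) == c(3L, 3L)) && all(is.finite(r)) &&
    max(abs(crossprod(r) - diag(3))) < tol && abs(det(r) - 1) < tol
}

#' Construct a unit quaternion
#'
#' Scalar-first Hamilton quaternion. The input is normalized and brought to
#' the canonical sign (`w >= 0`; if `w == 0` the first non-zero component is
#' made positive), so `q` and `-q` map to the same object.
#'
#' @param w,x,y,z Quaternion components, or `w` may be a length-4 vector.
#' @return A named numeric vector of class `"quat"` with unit norm.
#' @examples
#' quat(sqrt(2) / 2, 0, 0, sqrt(2) / 2) # 90 degrees about Z
#' @export
quat <- function(w, x = NULL, y = NULL, z = NULL) {
  q <- if (is.null(x)) as.numeric(w) else c(w, x, y, z)
  if (length(q) != 4L || !all(is.finite(q))) {
    stop("A quaternion needs 4 finite components (w, x, y, z).", call. = FALSE)
  }
  n <- sqrt(sum(q^2))
  if (n < 1e-12) {
    stop("Zero-norm quaternion is not a rotation.", call. = FALSE)
  }
  quat_canonical(q / n)
}

# canonical sign without revalidating; internal fast path
quat_canonical <- function(q) {
  nz <- which(abs(q) > 1e-12)
  if (length(nz) && q[nz[1L]] < 0) q <- -q
  names(q) <- c("w", "x", "y", "z")
  class(q) <- "quat"
  q
}

#' @export
print.quat <- function(x, ...) {
  cat(sprintf("<quat> w=%.6f x=%.6f y=%.6f z=%.6f\n", x[1], x[2], x[3], x[4]))
  invisible(x)
}

#' Hamilton product of two quaternions
#'
#' @param p,q Quaternions (scalar-first).
#' @return The unit product quaternion `p * q` in canonical form.
#' @export
quat_multiply <- function(p, q) {
  quat(
    p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1]
  )
}

#' Quaternion conjugate (inverse for unit quaternions)
#'
#' @param q A unit quaternion.
#' @return The conjugate quaternion in canonical form.
#' @export
quat_conjugate <- function(q) {
  quat(q[1], -q[2], -q[3], -q[4])
}

#' Convert a unit quaternion to a rotation matrix
#'
#' Standard Hamilton-convention conversion: the matrix rotates a vector by
#' the quaternion, `R(q) v`.
#'
#' @param q A unit quaternion (class `"quat"` or length-4 numeric).
#' @return A 3x3 proper rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- quat(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Shepperd's method: picks the numerically largest component first, then
#' returns the canonical-sign quaternion.
#'
#' @param r A 3x3 proper rotation matrix.
#' @return A unit quaternion of class `"quat"`.
#' @export
matrix_to_quat <- function(r) {
  if (!is_rotation_matrix(r, tol = 1e-6)) {
    stop("`r` is not a proper rotation matrix.", call. = FALSE)
  }
  tr <- r[1, 1] + r[2, 2] + r[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (r[3, 2] - r[2, 3]) / s, (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else if (r[1, 1] > r[2, 2] && r[1, 1] > r[3, 3]) {
    s <- sqrt(1 + r[1, 1] - r[2, 2] - r[3, 3]) * 2
    q <- c((r[3, 2] - r[2, 3]) / s, 0.25 * s, (r[1, 2] + r[2, 1]) / s,
           (r[1, 3] + r[3, 1]) / s)
  } else if (r[2, 2] > r[3, 3]) {
    s <- sqrt(1 + r[2, 2] - r[1, 1] - r[3, 3]) * 2
    q <- c((r[1, 3] - r[3, 1]) / s, (r[1, 2] + r[2, 1]) / s, 0.25 * s,
           (r[2, 3] + r[3, 2]) / s)
  } else {
    s <- sqrt(1 + r[3, 3] - r[1, 1] - r[2, 2]) * 2
    q <- c((r[2, 1] - r[1, 2]) / s, (r[1, 3] + r[3, 1]) / s,
           (r[2, 3] + r[3, 2]) / s, 0.25 * s)
  }
  quat(q)
}

#' Exponential map: rotation vector to quaternion
#'
#' @param v Rotation vector in degrees (axis times angle).
#' @return Unit quaternion of the rotation by `|v|` degrees about `v`.
#' @export
quat_from_rotvec <- function(v) {
  stopifnot(length(v) == 3L, all(is.finite(v)))
  angle <- sqrt(sum(v^2)) * DEG2RAD
  if (angle < 1e-14) {
    return(quat(1, 0, 0, 0))
  }
  axis <- v / sqrt(sum(v^2))
  quat(cos(angle / 2), axis[1] * sin(angle / 2), axis[2] * sin(angle / 2),
       axis[3] * sin(angle / 2))
}

#' Logarithmic map: quaternion to rotation vector
#'
#' @param q A unit quaternion.
#' @return Rotation vector in degrees, with angle in `[0, 180]`.
#' @export
quat_to_rotvec <- function(q) {
  q <- quat(q)
  vnorm <- sqrt(sum(q[2:4]^2))
  if (vnorm < 1e-14) {
    return(c(0, 0, 0))
  }
  angle <- 2 * atan2(vnorm, q[1]) * RAD2DEG
  unname((q[2:4] / vnorm) * angle)
}

#' Rotate a 3-vector by a quaternion
#'
#' @param q A unit quaternion.
#' @param v A 3-vector.
#' @return The rotated vector `R(q) v`.
#' @export
quat_rotate <- function(q, v) {
  as.numeric(quat_to_matrix(q) %*% v)
}

# --- Euler angles ----------------------------------------------------------

.axis_index <- c(X = 1L, Y = 2L, Z = 3L)

.check_order <- function(order) {
  order <- toupper(order)
  ax <- strsplit(order, "")[[1L]]
  if (length(ax) != 3L || !all(ax %in% c("X", "Y", "Z")) ||
      ax[1] == ax[2] || ax[2] == ax[3]) {
    stop("`order` must be three axis letters with no immediate repeat, ",
         "e.g. \"ZYX\".", call. = FALSE)
  }
  if (ax[1] == ax[3]) {
    stop("Proper-Euler sequences (repeated first/last axis) are not ",
         "supported; use a Tait-Bryan order such as \"ZYX\".", call. = FALSE)
  }
  ax
}

#' Euler angles to rotation matrix
#'
#' Intrinsic Tait-Bryan composition: with `order = "ZYX"` (the default,
#' yaw-pitch-roll) the result is `Rz(a1) %*% Ry(a2) %*% Rx(a3)`, each
#' successive rotation taken about the already-rotated axes.
#'
#' @param angles Length-3 numeric vector of angles in degrees, in the order
#'   given by `order`.
#' @param order Three-letter intrinsic axis sequence (Tait-Bryan, all six
#'   permutations of X, Y, Z supported). Default `"ZYX"`.
#' @return A 3x3 proper rotation matrix.
#' @examples
#' euler_to_matrix(c(45, 0, 0)) # yaw 45
#' @export
euler_to_matrix <- function(angles, order = "ZYX") {
  ax <- .check_order(order)
  stopifnot(length(angles) == 3L, all(is.finite(angles)))
  rot_axis(ax[1], angles[1]) %*% rot_axis(ax[2], angles[2]) %*%
    rot_axis(ax[3], angles[3])
}

#' Rotation matrix to Euler angles
#'
#' Inverse of [euler_to_matrix()] away from the gimbal band. In the band
#' (middle angle within `tol` of +/-90 degrees) the first and last rotations
#' share an axis and only their combination is observable: the last angle is
#' reported as 0, the first carries the combined rotation, and the
#' `"degenerate"` attribute is set to `TRUE`.
#'
#' @param r A 3x3 proper rotation matrix.
#' @param order Intrinsic Tait-Bryan axis sequence; see [euler_to_matrix()].
#' @param tol Closeness to the singular band that triggers the degenerate
#'   branch (on the sine of the middle angle).
#' @return Length-3 numeric vector of degrees in `(-180, 180]` with
#'   attributes `order` and `degenerate`.
#' @export
matrix_to_euler <- function(r, order = "ZYX", tol = 1e-9) {
  ax <- .check_order(order)
  if (!is_rotation_matrix(r, tol = 1e-6)) {
    stop("`r` is not a proper rotation matrix.", call. = FALSE)
  }
  i <- .axis_index[ax[1]]
  j <- .axis_index[ax[2]]
  k <- .axis_index[ax[3]]
  # parity of the axis sequence: +1 for even permutations of (X, Y, Z)
  eps <- if (((i - j) %% 3L) == 2L) 1 else -1
  s2 <- eps * r[i, k]
  s2 <- max(-1, min(1, s2))
  degenerate <- abs(s2) >= 1 - tol
  if (!degenerate) {
    a2 <- asin(s2) * RAD2DEG
    a1 <- atan2(-eps * r[j, k], r[k, k]) * RAD2DEG
    a3 <- atan2(-eps * r[i, j], r[i, i]) * RAD2DEG
  } else {
    a2 <- if (s2 > 0) 90 else -90
    a3 <- 0
    a1 <- atan2(r[j, i], r[j, j]) * RAD2DEG
  }
  out <- wrap_deg(c(a1, a2, a3))
  attr(out, "order") <- paste(ax, collapse = "")
  attr(out, "degenerate") <- degenerate
  out
}

#' Quaternion to Euler angles
#'
#' @inheritParams matrix_to_euler
#' @param q A unit quaternion.
#' @return As [matrix_to_euler()].
#' @export
quat_to_euler <- function(q, order = "ZYX") {
  matrix_to_euler(quat_to_matrix(q), order = order)
}

#' Euler angles to quaternion
#'
#' @inheritParams euler_to_matrix
#' @return A unit quaternion.
#' @export
euler_to_quat <- function(angles, order = "ZYX") {
  matrix_to_quat(euler_to_matrix(angles, order = order))
}
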
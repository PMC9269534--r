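# Joint-angle extraction: the forearm orientation is expressed in the arm
# frame and the rotations assigned to each analytical unit of movement are
# read off with atan2 projections. Flexion-extension (delta) is the
# sagittal-plane rotation about the anatomical Z axis; pronation-supination
# (Phi) the axial rotation of the forearm, read about X in the upright pose
# or about Y after 90 degrees of elbow flexion.

#' Relative rotation of the forearm in the arm frame
#'
#' `R_rel = t(R(q_arm)) %*% R(q_forearm)`: the forearm segment orientation
#' expressed in the arm segment frame. Identity when the two segments are
#' aligned (calibration pose).
#'
#' @param q_arm,q_forearm Unit quaternions (segment to anatomical).
#' @return A 3x3 rotation matrix.
#' @export
relative_rotation <- function(q_arm, q_forearm) {
  t(quat_to_matrix(q_arm)) %*% quat_to_matrix(q_forearm)
}

#' Flexion-extension angle from a relative rotation
#'
#' Projection onto the sagittal-plane rotation: `delta = atan2(R[2,1],
#' R[1,1])` in degrees, the exact inverse of the Z-axis rotation matrix on
#' axis and a stable projection off axis. Positive flexion raises the
#' forearm forward from the calibration pose.
#'
#' @param r_rel Relative rotation matrix from [relative_rotation()].
#' @return Angle in degrees in `(-180, 180]`.
#' @export
flexion_extension_angle <- function(r_rel) {
  atan2(r_rel[2, 1], r_rel[1, 1]) * RAD2DEG
}

#' Pronation-supination angle from a relative rotation
#'
#' Single-axis extraction per the rotation assigned to the movement:
#' in the `"upright"` pose the axial rotation is about the anatomical X
#' (vertical) axis, `Phi = atan2(R[3,2], R[2,2])`; with the elbow flexed to
#' 90 degrees (`"elbow_flexed_90"`) the forearm long axis lies along Y and
#' the same extraction is taken about Y, `Phi = atan2(R[1,3], R[3,3])`.
#' Positive pronation turns the palm down.
#'
#' @param r_rel Relative rotation matrix.
#' @param pose_mode `"upright"` or `"elbow_flexed_90"`.
#' @return Angle in degrees in `(-180, 180]`.
#' @export
pronation_supination_angle <- function(r_rel,
                                       pose_mode = c("upright",
                                                     "elbow_flexed_90")) {
  pose_mode <- match.arg(pose_mode)
  if (pose_mode == "upright") {
    atan2(r_rel[3, 2], r_rel[2, 2]) * RAD2DEG
  } else {
    atan2(r_rel[1, 3], r_rel[3, 3]) * RAD2DEG
  }
}

#' Unwrap an angle series
#'
#' Removes +/-360 degree jumps: successive differences larger than the
#' threshold are folded back, so a continuous motion crossing +/-180 stays
#' continuous.
#'
#' @param x Numeric vector of angles in degrees.
#' @param threshold Jump size (degrees) treated as a wrap (default 180).
#' @return The unwrapped series.
#' @export
unwrap_deg <- function(x, threshold = 180) {
  if (length(x) < 2L) {
    return(x)
  }
  d <- diff(x)
  adj <- numeric(length(d))
  adj[d > threshold] <- -360
  adj[d < -threshold] <- 360
  x + c(0, cumsum(adj))
}

#' Joint-angle series from two orientation tracks
#'
#' Per-sample extraction of elbow flexion-extension and forearm
#' pronation-supination from the arm and forearm orientation tracks. The
#' flexion angle is always the sagittal projection of the relative rotation.
#' For pronation, `"upright"` mode removes the measured flexion first and
#' reads the residual rotation about the forearm long axis (this reduces
#' exactly to the printed X-axis form at zero flexion and stays valid during
#' combined motion); `"elbow_flexed_90"` mode reads the Y-axis form directly.
#' Both channels are unwrapped, and flexion outside the physiologic band
#' `[-10, 180]` degrees is flagged, never clipped.
#'
#' @param arm,forearm `"orientation_track"` tibbles of equal length on the
#'   same time base.
#' @param pose_mode `"upright"`, `"elbow_flexed_90"`, or a character vector
#'   with one mode per sample.
#' @return A tibble of class `"joint_angles"`: `t`, `flexion_extension`,
#'   `pronation_supination` (degrees), `pose_mode`, `off_axis` (degrees of
#'   rotation not explained by the two assigned axes) and `outside_band`.
#' @export
angle_series <- function(arm, forearm, pose_mode = "upright") {
  n <- nrow(forearm)
  if (nrow(arm) != n) {
    stop("Arm and forearm tracks differ in length (", nrow(arm), " vs ",
         n, ").", call. = FALSE)
  }
  if (max(abs(arm$t - forearm$t)) > 1e-9) {
    stop("Arm and forearm tracks are not on the same time base.",
         call. = FALSE)
  }
  if (length(pose_mode) == 1L) {
    pose_mode <- rep(pose_mode, n)
  }
  stopifnot(length(pose_mode) == n,
            all(pose_mode %in% c("upright", "elbow_flexed_90")))
  qa <- as.matrix(arm[, c("qw", "qx", "qy", "qz")])
  qf <- as.matrix(forearm[, c("qw", "qx", "qy", "qz")])
  fe <- numeric(n)
  ps <- numeric(n)
  off <- numeric(n)
  for (i in seq_len(n)) {
    R <- relative_rotation(quat(qa[i, ]), quat(qf[i, ]))
    d <- atan2(R[2, 1], R[1, 1]) * RAD2DEG
    if (pose_mode[i] == "upright") {
      # residual axial rotation after removing the measured flexion
      Mres <- t(rot_axis("Z", d)) %*% R
      p <- atan2(Mres[3, 2], Mres[2, 2]) * RAD2DEG
      recon <- rot_axis("Z", d) %*% rot_axis("X", p)
    } else {
      p <- atan2(R[1, 3], R[3, 3]) * RAD2DEG
      # flexed-pose model: flexion about Z, then axial rotation about the
      # forearm long axis (intrinsic X), which equals Ry(p) Rz(d)
      recon <- rot_axis("Y", p) %*% rot_axis("Z", d)
    }
    fe[i] <- d
    ps[i] <- p
    off[i] <- sqrt(sum(quat_to_rotvec(matrix_to_quat(t(recon) %*% R))^2))
  }
  fe <- unwrap_deg(fe)
  ps <- unwrap_deg(ps)
  out <- tibble::tibble(
    t = forearm$t,
    flexion_extension = fe,
    pronation_supination = ps,
    pose_mode = pose_mode,
    off_axis = off,
    outside_band = fe < -10 | fe > 180
  )
  class(out) <- c("joint_angles", class(out))
  out
}

#' Range-of-motion summary per movement channel
#'
#' Minimum, maximum, range and repetition count for each angle channel.
#' Repetitions are excursions across the mid-range with hysteresis: a
#' repetition is counted each time the signal rises above
#' `mid + hysteresis/2` and later falls below `mid - hysteresis/2`, with
#' `hysteresis` a fraction of the range, making the count robust to noise.
#'
#' @param series A `"joint_angles"` tibble (or any tibble with `t` and angle
#'   columns).
#' @param channels Angle columns to summarise.
#' @param hysteresis Fraction of the range used as the hysteresis band
#'   (default 0.2).
#' @param min_range Ranges below this (degrees) report zero repetitions.
#' @return A tibble with one row per channel: `channel`, `min`, `max`,
#'   `range`, `repetitions`, `n`.
#' @export
rom_summary <- function(series,
                        channels = c("flexion_extension",
                                     "pronation_supination"),
                        hysteresis = 0.2, min_range = 1) {
  if (nrow(series) < 1L) {
    stop("Cannot summarise an empty series.", call. = FALSE)
  }
  purrr::map_dfr(channels, function(ch) {
    x <- series[[ch]]
    lo <- min(x)
    hi <- max(x)
    rng <- hi - lo
    reps <- 0L
    if (rng >= min_range) {
      mid <- (lo + hi) / 2
      band <- hysteresis * rng / 2
      state <- "low"
      for (v in x) {
        if (state == "low" && v > mid + band) {
          state <- "high"
        } else if (state == "high" && v < mid - band) {
          state <- "low"
          reps <- reps + 1L
        }
      }
    }
    tibble::tibble(channel = ch, min = lo, max = hi, range = rng,
                   repetitions = reps, n = length(x))
  })
}
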
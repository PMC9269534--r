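# Forward simulation of a two-sensor upper-limb capture: commanded joint
# angles -> segment orientations -> exact per-sample gyro increments and
# gravity/field/linear-acceleration readings in each mounted sensor frame,
# plus seeded noise. The generator is first-class: its ground truth is the
# oracle for every end-to-end test of the pipeline.

#' Movement protocol for a simulated session
#'
#' An ordered table of movement phases. Each phase commands one analytical
#' unit of movement (elbow flexion-extension or forearm
#' pronation-supination) between two angles for a number of repetitions,
#' one out-and-back repetition per period.
#'
#' @param movement Character vector: `"flexion_extension"` or
#'   `"pronation_supination"`.
#' @param start_deg,end_deg Commanded angle endpoints in degrees.
#' @param repetitions Repetitions per phase (>= 1).
#' @param period_s Seconds per repetition (> 0).
#' @param profile Velocity profile, `"cosine"` (raised cosine, default) or
#'   `"trapezoid"`.
#' @param pose_mode Pose context for pronation extraction: `"upright"` or
#'   `"elbow_flexed_90"`.
#' @param flexion_hold_deg Constant elbow flexion held during the phase
#'   (90 for the flexed pronation block, else 0).
#' @return A tibble of class `"motion_protocol"`.
#' @export
motion_protocol <- function(movement, start_deg, end_deg, repetitions,
                            period_s, profile = "cosine",
                            pose_mode = "upright", flexion_hold_deg = 0) {
  out <- tibble::tibble(
    movement = movement, start_deg = start_deg, end_deg = end_deg,
    repetitions = as.integer(repetitions), period_s = period_s,
    profile = profile, pose_mode = pose_mode,
    flexion_hold_deg = flexion_hold_deg
  )
  stopifnot(
    all(out$movement %in% c("flexion_extension", "pronation_supination")),
    all(out$repetitions >= 1L), all(out$period_s > 0),
    all(out$profile %in% c("cosine", "trapezoid")),
    all(out$pose_mode %in% c("upright", "elbow_flexed_90"))
  )
  class(out) <- c("motion_protocol", class(out))
  out
}

#' The standard validation protocol
#'
#' Three phases of five repetitions each: elbow flexion from ~0 to ~90
#' degrees and back; flexion from ~0 to the maximum and back; and
#' pronation-supination between -max and +max with the elbow flexed to 90
#' degrees. The maxima are subject-dependent; the defaults (145 degrees
#' flexion, 80 degrees each way of axial rotation) are conventional
#' physiologic values. The default period reproduces a session of about
#' 45 s at 60 Hz including the 2 s static calibration segment.
#'
#' @param max_flexion Peak flexion of the second phase, degrees.
#' @param max_prosup Pronation-supination amplitude (each way), degrees.
#' @param repetitions Repetitions per phase.
#' @param period_s Seconds per repetition.
#' @return A `"motion_protocol"` with three phases.
#' @export
protocol_standard <- function(max_flexion = 145, max_prosup = 80,
                            repetitions = 5, period_s = 2.82) {
  motion_protocol(
    movement = c("flexion_extension", "flexion_extension",
                 "pronation_supination"),
    start_deg = c(0, 0, -max_prosup),
    end_deg = c(90, max_flexion, max_prosup),
    repetitions = rep(repetitions, 3),
    period_s = rep(period_s, 3),
    pose_mode = c("upright", "upright", "elbow_flexed_90"),
    flexion_hold_deg = c(0, 0, 90)
  )
}

#' Sensor noise model
#'
#' Additive white Gaussian noise per channel plus a constant gyro bias,
#' applied in the sensor frame. The same seed always yields bit-identical
#' streams.
#'
#' @param preset `"default"` (accel 0.05 m/s^2, gyro 0.2 deg/s, gyro bias of
#'   0.5 deg/s magnitude, mag 0.5 uT) or `"none"` (all zero). Explicit
#'   arguments override the preset.
#' @param accel_sigma Accelerometer noise sd, m/s^2.
#' @param gyro_sigma Gyroscope noise sd, deg/s.
#' @param gyro_bias Constant gyro bias 3-vector, deg/s (sensor frame).
#' @param mag_sigma Magnetometer noise sd, microtesla.
#' @param seed Integer RNG seed; `NULL` uses the ambient RNG state.
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(preset = c("default", "none"), accel_sigma = NULL,
                        gyro_sigma = NULL, gyro_bias = NULL,
                        mag_sigma = NULL, seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "default") {
    list(accel_sigma = 0.05, gyro_sigma = 0.2,
         gyro_bias = rep(0.5 / sqrt(3), 3), mag_sigma = 0.5)
  } else {
    list(accel_sigma = 0, gyro_sigma = 0, gyro_bias = c(0, 0, 0),
         mag_sigma = 0)
  }
  out <- list(
    accel_sigma = accel_sigma %||% def$accel_sigma,
    gyro_sigma = gyro_sigma %||% def$gyro_sigma,
    gyro_bias = gyro_bias %||% def$gyro_bias,
    mag_sigma = mag_sigma %||% def$mag_sigma,
    seed = seed
  )
  stopifnot(out$accel_sigma >= 0, out$gyro_sigma >= 0, out$mag_sigma >= 0,
            length(out$gyro_bias) == 3L)
  class(out) <- "noise_model"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# out-and-back position shape on [0, 1): 0 -> 1 -> 0
.rep_shape <- function(u, profile) {
  if (profile == "cosine") {
    (1 - cos(2 * pi * u)) / 2
  } else {
    half <- ifelse(u <= 0.5, 2 * u, 2 * (1 - u))
    .trap_half(half)
  }
}

# monotone 0 -> 1 with trapezoidal velocity (25 % accel / decel)
.trap_half <- function(v) {
  ta <- 0.25
  k <- 1 / (ta * (1 - ta))
  ifelse(v < ta, 0.5 * k * v^2,
    ifelse(v < 1 - ta, (v - ta / 2) / (1 - ta),
           1 - 0.5 * k * (1 - v)^2))
}

# signed 0 -> +1 -> -1 -> 0 shape for pronation-supination repetitions
.prosup_shape <- function(u, profile) {
  if (profile == "cosine") {
    sin(2 * pi * u)
  } else {
    ifelse(u < 0.25, .trap_half(4 * u),
      ifelse(u < 0.75, 1 - 2 * .trap_half(2 * (u - 0.25)),
             -1 + .trap_half(4 * (u - 0.75))))
  }
}

# commanded (flexion, pronation, mode) at each time; piecewise over segments
.command_angles <- function(protocol, t, t_cal, transition_s) {
  n <- length(t)
  fe <- numeric(n)
  ps <- numeric(n)
  mode <- rep("upright", n)
  segs <- list()
  t0 <- t_cal
  hold <- 0
  if (!is.null(protocol) && nrow(protocol) > 0L) {
    for (i in seq_len(nrow(protocol))) {
      ph <- protocol[i, ]
      new_hold <- ph$flexion_hold_deg
      if (new_hold != hold && transition_s > 0) {
        segs[[length(segs) + 1L]] <- list(kind = "transition", t0 = t0,
                                          dur = transition_s, from = hold,
                                          to = new_hold,
                                          mode = ph$pose_mode)
        t0 <- t0 + transition_s
      }
      hold <- new_hold
      segs[[length(segs) + 1L]] <- list(kind = "phase", t0 = t0,
                                        dur = ph$repetitions * ph$period_s,
                                        phase = ph)
      t0 <- t0 + ph$repetitions * ph$period_s
    }
  }
  for (seg in segs) {
    idx <- which(t >= seg$t0 - 1e-12 & t < seg$t0 + seg$dur - 1e-12)
    if (!length(idx)) next
    tau <- t[idx] - seg$t0
    if (seg$kind == "transition") {
      fe[idx] <- seg$from + (seg$to - seg$from) *
        (1 - cos(pi * tau / seg$dur)) / 2
      mode[idx] <- seg$mode
    } else {
      ph <- seg$phase
      u <- (tau / ph$period_s) %% 1
      if (ph$movement == "flexion_extension") {
        fe[idx] <- ph$start_deg + (ph$end_deg - ph$start_deg) *
          .rep_shape(u, ph$profile)
        ps[idx] <- 0
      } else {
        mid <- (ph$start_deg + ph$end_deg) / 2
        amp <- (ph$end_deg - ph$start_deg) / 2
        ps[idx] <- mid + amp * .prosup_shape(u, ph$profile)
        fe[idx] <- ph$flexion_hold_deg
      }
      mode[idx] <- ph$pose_mode
    }
  }
  # anything past the last segment holds the final command
  if (length(segs)) {
    last <- segs[[length(segs)]]
    idx <- which(t >= last$t0 + last$dur - 1e-12)
    if (length(idx) && nrow(protocol) > 0L) {
      ph <- protocol[nrow(protocol), ]
      fe[idx] <- ph$flexion_hold_deg
      if (ph$movement == "flexion_extension") fe[idx] <- ph$start_deg
      mode[idx] <- ph$pose_mode
    }
  }
  list(fe = fe, ps = ps, mode = mode, duration = t0)
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a two-sensor upper-limb capture session
#'
#' Builds the segment orientation trajectories commanded by the protocol
#' (arm fixed; forearm flexed about the anatomical Z axis and axially
#' rotated about its own long axis), prepends a static calibration-pose
#' segment, and derives per-sample sensor readings in each mounted sensor
#' frame: angular velocity from exact finite rotation increments,
#' acceleration as the gravity reaction plus the linear-acceleration term of
#' a two-link geometry, and the earth magnetic field. Seeded noise and gyro
#' bias are then added.
#'
#' @param protocol A `"motion_protocol"` (default [protocol_standard()]);
#'   `NULL` for a static-only session.
#' @param rate Sampling rate in Hz: 30, 60 or 120.
#' @param noise A [noise_model()].
#' @param mounts Actual sensor placements (possibly perturbed with
#'   [perturb_mounting()]); the calibration step is told only the nominal
#'   mounts.
#' @param t_cal Seconds of static calibration pose prepended (default 2).
#' @param transition_s Seconds of smooth flexion transition inserted when a
#'   phase requires a different held elbow angle (default 1).
#' @param arm_length,forearm_length Segment lengths in metres (two-link
#'   geometry for the linear-acceleration term).
#' @param sensor_offset Lateral offset of the forearm sensor from the
#'   segment long axis, metres (skin surface, not the bone axis).
#' @param field_magnitude,field_dip Earth magnetic field, microtesla and
#'   degrees of dip.
#' @param seed Overrides `noise$seed` when not `NULL`.
#' @return An object of class `"imu_session"`: ground-truth `truth` tibble
#'   (`t`, `flexion_extension`, `pronation_supination`, `pose_mode`), raw
#'   `arm` and `forearm` streams, true segment quaternions, and the
#'   generating configuration.
#' @examples
#' s <- simulate_session(protocol = NULL, t_cal = 1, rate = 60,
#'                       noise = noise_model("none"))
#' nrow(s$arm) # 60 samples
#' @export
simulate_session <- function(protocol = protocol_standard(), rate = 60,
                             noise = noise_model("default"),
                             mounts = default_mounts(), t_cal = 2,
                             transition_s = 1,
                             arm_length = 0.28, forearm_length = 0.25,
                             sensor_offset = 0.03,
                             field_magnitude = 48, field_dip = 35,
                             seed = NULL) {
  stopifnot(rate %in% c(30, 60, 120), t_cal >= 0)
  no_motion <- is.null(protocol) || nrow(protocol) == 0L
  if (no_motion && t_cal <= 0) {
    stop("Empty session: no protocol phases and no calibration segment.",
         call. = FALSE)
  }
  # provisional long grid to learn the duration, then cut
  t_probe <- seq(0, 3600, by = 1 / rate)
  cmd <- .command_angles(protocol, t_probe, t_cal, transition_s)
  duration <- cmd$duration
  n <- as.integer(round(duration * rate))
  t <- (seq_len(n) - 1L) / rate
  fe <- cmd$fe[seq_len(n)]
  ps <- cmd$ps[seq_len(n)]
  mode <- cmd$mode[seq_len(n)]

  g_anat <- c(GRAVITY, 0, 0)                    # gravity points down = +X
  b_anat <- anatomical_field(field_magnitude, field_dip)

  # forearm orientation: flexion about Z, then axial rotation about the
  # rotated (intrinsic) X axis, the forearm long axis
  quat_f <- matrix(0, n, 4)
  Rf <- vector("list", n)
  for (i in seq_len(n)) {
    Rf[[i]] <- rot_axis("Z", fe[i]) %*% rot_axis("X", ps[i])
    quat_f[i, ] <- matrix_to_quat(Rf[[i]])
  }
  quat_a <- matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE)

  dt <- 1 / rate
  # body-frame angular velocity from exact rotation increments
  omega_f <- matrix(0, n, 3)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      omega_f[i, ] <- quat_to_rotvec(
        matrix_to_quat(t(Rf[[i]]) %*% Rf[[i + 1L]])
      ) / dt
    }
    omega_f[n, ] <- omega_f[n - 1L, ]
  }

  # linear acceleration of the forearm sensor (elbow is the fixed origin;
  # the arm is stationary, so its sensor has none)
  r_local <- c(2 / 3 * forearm_length, 0, sensor_offset)
  pos <- t(vapply(Rf, function(R) as.numeric(R %*% r_local), numeric(3)))
  a_lin <- matrix(0, n, 3)
  if (n > 2L) {
    core <- 2:(n - 1L)
    a_lin[core, ] <- (pos[core + 1L, ] - 2 * pos[core, ] +
                        pos[core - 1L, ]) / dt^2
  }

  make_stream <- function(which) {
    R_place <- mounts[[which]]$R
    sensor_id <- mounts[[which]]$sensor_id
    acc <- matrix(0, n, 3)
    gyr <- matrix(0, n, 3)
    mag <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      Q <- if (which == "forearm") Rf[[i]] else diag(3)
      G <- Q %*% R_place
      f_anat <- (if (which == "forearm") a_lin[i, ] else c(0, 0, 0)) - g_anat
      acc[i, ] <- crossprod(G, f_anat)
      mag[i, ] <- crossprod(G, b_anat)
      w_seg <- if (which == "forearm") omega_f[i, ] else c(0, 0, 0)
      gyr[i, ] <- crossprod(R_place, w_seg)
    }
    acc <- acc + matrix(stats::rnorm(3 * n, sd = noise$accel_sigma), n, 3)
    gyr <- gyr + matrix(stats::rnorm(3 * n, sd = noise$gyro_sigma), n, 3) +
      matrix(noise$gyro_bias, n, 3, byrow = TRUE)
    mag <- mag + matrix(stats::rnorm(3 * n, sd = noise$mag_sigma), n, 3)
    imu_stream(t, acc, gyr, mag, rate = rate, sensor_id = sensor_id)
  }

  use_seed <- seed %||% noise$seed
  streams <- .with_seed(use_seed, list(arm = make_stream("arm"),
                                       forearm = make_stream("forearm")))

  truth <- tibble::tibble(t = t, flexion_extension = fe,
                          pronation_supination = ps, pose_mode = mode)
  class(truth) <- c("joint_angles", class(truth))
  out <- list(
    truth = truth, arm = streams$arm, forearm = streams$forearm,
    quat_arm = quat_a, quat_forearm = quat_f,
    rate = rate, t_cal = t_cal, protocol = protocol, noise = noise,
    mounts = mounts, seed = use_seed, duration = duration
  )
  class(out) <- "imu_session"
  out
}

#' @export
print.imu_session <- function(x, ...) {
  cat("<imu_session>\n")
  cat(sprintf("  %.2f s at %d Hz (%d samples/sensor), %.1f s calibration pose\n",
              x$duration, x$rate, nrow(x$arm), x$t_cal))
  if (!is.null(x$protocol) && nrow(x$protocol) > 0L) {
    cat(sprintf("  %d protocol phases, seed %s\n", nrow(x$protocol),
                format(x$seed)))
  } else {
    cat("  static-only session\n")
  }
  invisible(x)
}

#' Ground-truth joint angles of a simulated session
#'
#' @param session An `"imu_session"`.
#' @return The commanded `"joint_angles"` tibble on the session time base.
#' @export
truth_export <- function(session) {
  stopifnot(inherits(session, "imu_session"))
  session$truth
}

#' Run the full recovery pipeline on a session
#'
#' Calibrates from the static head of the session streams (using the
#' nominal mounting configuration), fuses both sensors, and extracts the
#' joint-angle series with the protocol's pose modes. This is the
#' end-to-end path a live capture would take.
#'
#' @param session An `"imu_session"`.
#' @param mounts Nominal (configured) mounting pair given to calibration;
#'   defaults to the standard mounts, which differ from `session$mounts`
#'   when the simulated placement was perturbed.
#' @param params [fusion_params()] for the attitude filter.
#' @param calib Optional precomputed `"elbow_calibration"`; when `NULL` it
#'   is estimated from the first `session$t_cal` seconds.
#' @return A `"joint_angles"` tibble.
#' @export
recover_angles <- function(session, mounts = default_mounts(),
                           params = fusion_params(), calib = NULL) {
  stopifnot(inherits(session, "imu_session"))
  if (is.null(calib)) {
    head_idx <- session$arm$t < session$t_cal - 1e-9
    if (!any(head_idx)) {
      stop("Session has no static calibration segment; supply `calib`.",
           call. = FALSE)
    }
    calib <- calibrate(session$arm[head_idx, ], session$forearm[head_idx, ],
                       mounts = mounts)
  }
  arm_track <- fuse_stream(session$arm, calib = calib, params = params,
                           sensor = "arm")
  forearm_track <- fuse_stream(session$forearm, calib = calib,
                               params = params, sensor = "forearm")
  angle_series(arm_track, forearm_track, pose_mode = session$truth$pose_mode)
}
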
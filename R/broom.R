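# broom-style accessors for fitted/derived objects.

#' Tidy a calibration result
#'
#' One row per sensor with the residual correction angle carried by the
#' calibration matrix, the configured mounting deltas, and the static mean
#' vector norms.
#'
#' @param x An `"elbow_calibration"`.
#' @param ... Unused.
#' @return A tibble with columns `sensor`, `sensor_id`, `correction_deg`,
#'   `delta1`, `delta2`, `mean_accel`, `mean_field`, `n`.
#' @export
tidy.elbow_calibration <- function(x, ...) {
  ang <- function(M) sqrt(sum(quat_to_rotvec(matrix_to_quat(M))^2))
  purrr::map_dfr(c("arm", "forearm"), function(s) {
    M <- if (s == "arm") x$M1 else x$M2
    tibble::tibble(
      sensor = s,
      sensor_id = x$mounts[[s]]$sensor_id,
      correction_deg = ang(M),
      delta1 = x$mounts[[s]]$delta[1],
      delta2 = x$mounts[[s]]$delta[2],
      mean_accel = sqrt(sum(x$mean_a[[s]]^2)),
      mean_field = sqrt(sum(x$mean_b[[s]]^2)),
      n = unname(x$n[s])
    )
  })
}

#' Glance at a calibration result
#'
#' @param x An `"elbow_calibration"`.
#' @param ... Unused.
#' @return A one-row tibble: arm correction angle, deviation of the mean
#'   static acceleration norm from 1 g, and sample counts.
#' @export
glance.elbow_calibration <- function(x, ...) {
  tibble::tibble(
    arm_correction_deg = sqrt(sum(quat_to_rotvec(matrix_to_quat(x$M1))^2)),
    gravity_residual = abs(sqrt(sum(x$mean_a$forearm^2)) - GRAVITY),
    n_arm = unname(x$n["arm"]),
    n_forearm = unname(x$n["forearm"])
  )
}

#' Tidy a two-system comparison
#'
#' @param x A `"rom_comparison"`.
#' @param ... Unused.
#' @return The per-channel metric tibble.
#' @export
tidy.rom_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Glance at a two-system comparison
#'
#' @param x A `"rom_comparison"`.
#' @param ... Unused.
#' @return A one-row tibble with the mean and worst RMSE across channels.
#' @export
glance.rom_comparison <- function(x, ...) {
  tibble::tibble(
    mean_rmse = mean(x$rmse),
    max_rmse = max(x$rmse),
    mean_abs_bias = mean(abs(x$bias)),
    channels = nrow(x)
  )
}
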
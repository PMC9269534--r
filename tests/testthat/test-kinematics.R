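test_that("relative rotation expresses the forearm in the arm frame", {
  q <- matrix_to_quat(random_rotation())
  expect_equal(relative_rotation(q, q), diag(3), tolerance = 1e-9)
  qz <- matrix_to_quat(rot_axis("Z", 35))
  expect_equal(relative_rotation(quat(1, 0, 0, 0), qz), rot_axis("Z", 35),
               tolerance = 1e-9)
  # independent quaternion-algebra oracle: conjugate product
  set.seed(31)
  for (i in 1:20) {
    qa <- matrix_to_quat(random_rotation())
    qf <- matrix_to_quat(random_rotation())
    via_quat <- quat_to_matrix(quat_multiply(quat_conjugate(qa), qf))
    expect_equal(relative_rotation(qa, qf), via_quat, tolerance = 1e-9)
  }
})

test_that("flexion extraction inverts the sagittal rotation on axis", {
  expect_equal(flexion_extension_angle(diag(3)), 0)
  expect_equal(flexion_extension_angle(rot_axis("Z", 90)), 90)
  for (d in seq(-175, 180, by = 5)) {
    expect_equal(flexion_extension_angle(rot_axis("Z", d)), d,
                 tolerance = 1e-9)
  }
  # small off-axis content barely disturbs the projection: compare with a
  # numeric argmin oracle over the upper-left 2x2 block
  R <- rot_axis("Z", 30) %*% rot_axis("X", 1)
  oracle <- stats::optimize(function(d) {
    sum((R[1:2, 1:2] - rot_axis("Z", d)[1:2, 1:2])^2)
  }, c(0, 60))$minimum
  expect_equal(flexion_extension_angle(R), 30, tolerance = 0.1)
  expect_equal(flexion_extension_angle(R), oracle, tolerance = 0.01)
})

test_that("pronation extraction follows the pose-dependent axis", {
  expect_equal(pronation_supination_angle(diag(3)), 0)
  expect_equal(pronation_supination_angle(rot_axis("X", 45), "upright"), 45)
  expect_equal(
    pronation_supination_angle(rot_axis("Y", 60), "elbow_flexed_90"), 60
  )
  for (p in seq(-170, 170, by = 10)) {
    expect_equal(pronation_supination_angle(rot_axis("X", p), "upright"), p,
                 tolerance = 1e-9)
  }
})

test_that("angle series reproduces constructed ramps and flags bands", {
  n <- 50
  t <- (seq_len(n) - 1) / 60
  idq <- matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE)
  arm <- orientation_track(t, idq)
  # both identity -> all zero
  ser0 <- angle_series(arm, arm)
  expect_true(all(ser0$flexion_extension == 0))
  expect_true(all(ser0$pronation_supination == 0))
  # forearm Rz ramp 0 -> 90
  ramp <- seq(0, 90, length.out = n)
  qf <- t(vapply(ramp, function(d) as.numeric(matrix_to_quat(rot_axis("Z", d))),
                 numeric(4)))
  ser <- angle_series(arm, orientation_track(t, qf))
  expect_equal(ser$flexion_extension, ramp, tolerance = 1e-6)
  expect_equal(ser$pronation_supination, rep(0, n), tolerance = 1e-6)
  expect_false(any(ser$outside_band))
  # hyperextension past the physiologic band is flagged, not clipped
  qh <- t(vapply(c(-20, 5), function(d) {
    as.numeric(matrix_to_quat(rot_axis("Z", d)))
  }, numeric(4)))
  arm2 <- orientation_track(t[1:2], idq[1:2, , drop = FALSE])
  serh <- angle_series(arm2, orientation_track(t[1:2], qh))
  expect_equal(serh$outside_band, c(TRUE, FALSE))
  expect_equal(serh$flexion_extension[1], -20, tolerance = 1e-6)
  expect_error(angle_series(arm, arm2), "length")
})

test_that("pronation reads correctly through held flexion in both modes", {
  # flexed-pose composition: flexion 90 about Z then axial rotation
  for (p in c(-60, 0, 45, 80)) {
    R <- rot_axis("Z", 90) %*% rot_axis("X", p)
    q_arm <- quat(1, 0, 0, 0)
    q_fore <- matrix_to_quat(R)
    ser <- angle_series(
      orientation_track(0, matrix(as.numeric(q_arm), 1)),
      orientation_track(0, matrix(as.numeric(q_fore), 1)),
      pose_mode = "elbow_flexed_90"
    )
    expect_equal(ser$flexion_extension, 90, tolerance = 1e-6)
    expect_equal(ser$pronation_supination, p, tolerance = 1e-6)
    # upright (residual) mode agrees on this composition
    ser2 <- angle_series(
      orientation_track(0, matrix(as.numeric(q_arm), 1)),
      orientation_track(0, matrix(as.numeric(q_fore), 1)),
      pose_mode = "upright"
    )
    expect_equal(ser2$pronation_supination, p, tolerance = 1e-6)
  }
  # deep flexion alone must not leak into the pronation channel
  R145 <- rot_axis("Z", 145)
  ser3 <- angle_series(
    orientation_track(0, matrix(c(1, 0, 0, 0), 1)),
    orientation_track(0, matrix(as.numeric(matrix_to_quat(R145)), 1)),
    pose_mode = "upright"
  )
  expect_equal(ser3$pronation_supination, 0, tolerance = 1e-6)
})

test_that("ground-truth orientations reproduce the commanded protocol", {
  s <- standard_noiseless()
  tru <- truth_export(s)
  ser <- angle_series(orientation_track(tru$t, s$quat_arm),
                      orientation_track(tru$t, s$quat_forearm),
                      pose_mode = tru$pose_mode)
  expect_lt(rmse(ser$flexion_extension, tru$flexion_extension), 1e-6)
  expect_lt(rmse(ser$pronation_supination, tru$pronation_supination), 1e-6)
  expect_lt(max(ser$off_axis), 1e-6)
})

test_that("unwrapping removes 360-degree jumps", {
  x <- c(170, 175, 180, -175, -170)
  u <- unwrap_deg(x)
  expect_equal(u, c(170, 175, 180, 185, 190))
  expect_equal(diff(u), diff(c(170, 175, 180, 185, 190)))
  expect_equal(unwrap_deg(c(5)), 5)
})

test_that("rom summary counts repetitions with hysteresis", {
  # constant series: zero range, zero repetitions
  const <- tibble::tibble(t = 1:10 / 60, flexion_extension = rep(5, 10),
                          pronation_supination = rep(0, 10))
  rs <- rom_summary(const)
  expect_equal(rs$range, c(0, 0))
  expect_equal(rs$repetitions, c(0L, 0L))
  # triangle wave 0 -> 90 -> 0, five cycles
  tri <- rep(c(seq(0, 90, by = 5), seq(85, 5, by = -5)), 5)
  ser <- tibble::tibble(t = seq_along(tri) / 60, flexion_extension = tri,
                        pronation_supination = 0)
  rs2 <- rom_summary(ser)
  fe <- rs2[rs2$channel == "flexion_extension", ]
  expect_equal(fe$min, 0)
  expect_equal(fe$max, 90)
  expect_equal(fe$range, 90)
  expect_equal(fe$repetitions, 5L)
  # robust to 1-degree noise
  set.seed(6)
  ser$flexion_extension <- tri + stats::rnorm(length(tri), sd = 1)
  rs3 <- rom_summary(ser)
  expect_equal(rs3$repetitions[rs3$channel == "flexion_extension"], 5L)
  expect_error(rom_summary(const[0, ]), "empty")
})
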
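test_that("frame transform rotates all three vector channels and keeps norms", {
  s <- static_session(0.5)$arm
  expect_equal(transform_stream(s), s)
  M <- rot_axis("Z", 90)
  out <- transform_stream(tibble::tibble(
    t = 0, k = 0L, ax = 1, ay = 0, az = 0, gx = 0, gy = 0, gz = 0,
    mx = 2, my = 0, mz = 0
  ), M = M)
  expect_equal(c(out$ax, out$ay, out$az), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(c(out$mx, out$my, out$mz), c(0, 2, 0), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    R <- random_rotation()
    tr <- transform_stream(s, R = R)
    expect_equal(sqrt(tr$ax^2 + tr$ay^2 + tr$az^2),
                 sqrt(s$ax^2 + s$ay^2 + s$az^2), tolerance = 1e-9)
    expect_equal(sqrt(tr$mx^2 + tr$my^2 + tr$mz^2),
                 sqrt(s$mx^2 + s$my^2 + s$mz^2), tolerance = 1e-9)
  }
})

test_that("static means are component-wise arithmetic means", {
  mk <- function(a) imu_stream(seq_len(nrow(a)) / 60, a,
                               matrix(0, nrow(a), 3), matrix(5, nrow(a), 3))
  mv <- mean_vectors(mk(matrix(rep(c(0, 0, 9.81), 4), 4, 3, byrow = TRUE)))
  expect_equal(mv$mean_a, c(0, 0, 9.81))
  mv2 <- mean_vectors(mk(rbind(c(0, 0, 9), c(0, 0, 11))))
  expect_equal(mv2$mean_a, c(0, 0, 10))
  mv3 <- mean_vectors(mk(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))))
  expect_equal(mv3$mean_a, rep(1 / 3, 3))
  expect_error(mean_vectors(mk(matrix(0, 4, 3))[0, ]), "empty")
})

test_that("gravity/field basis construction is orthonormal and right-handed", {
  b <- build_basis(c(0, 0, 2), c(3, 0, 0))
  expect_equal(b$v1, c(0, 0, 1))
  expect_equal(b$v2, c(0, 1, 0))
  expect_equal(b$v3, c(-1, 0, 0))
  set.seed(5)
  for (i in 1:25) {
    ba <- stats::rnorm(3) * 5
    bb <- stats::rnorm(3) * 30
    if (sqrt(sum(ba^2)) < 1e-3) next
    bs <- build_basis(ba, bb)
    expect_lt(max(abs(crossprod(bs$B) - diag(3))), 1e-9)
    expect_equal(det(bs$B), 1, tolerance = 1e-9)
  }
  expect_error(build_basis(c(0, 0, 0), c(3, 0, 0)), "gravity")
  expect_error(build_basis(c(0, 0, 9.81), c(0, 0, 50)), "field")
})

test_that("calibration matrix is identity for the reference sensor and the
          orthonormal inverse for the arm", {
  b1 <- build_basis(c(0, 1, 0.2), c(30, 1, 2))
  expect_equal(calibration_matrix(b1, b1, 1L), diag(3), tolerance = 1e-12)
  expect_equal(calibration_matrix(b1, build_basis(c(1, 2, 3), c(9, -1, 0)),
                                  2L), diag(3))
  # basis_2 = identity columns, basis_1 = columns of Rz(90): brute-force
  # 3x3 inversion agrees with the transpose shortcut
  R <- rot_axis("Z", 90)
  b2 <- list(B = diag(3))
  bi <- list(B = R)
  M <- calibration_matrix(bi, b2, 1L)
  expect_equal(M, rot_axis("Z", -90), tolerance = 1e-12)
  expect_equal(M, b2$B %*% solve(bi$B), tolerance = 1e-12)
})

test_that("perfect mounting calibrates to the identity", {
  s <- static_session(1)
  cal <- calibrate(s$arm, s$forearm)
  expect_lt(max(abs(cal$M1 - diag(3))), 1e-9)
  expect_identical(cal$M2, diag(3))
})

test_that("single-sample captures calibrate (means degenerate to the sample)", {
  s <- static_session(1)
  cal <- calibrate(s$arm[1, ], s$forearm[1, ])
  expect_lt(max(abs(cal$M1 - diag(3))), 1e-9)
})

test_that("calibration is invariant to sample order within a capture", {
  s <- standard_noisy(3)
  head_arm <- s$arm[s$arm$t < 2, ]
  head_fore <- s$forearm[s$forearm$t < 2, ]
  cal1 <- calibrate(head_arm, head_fore)
  # reversal leaves the static means, hence the matrices, unchanged
  rev_arm <- head_arm[rev(seq_len(nrow(head_arm))), ]
  rev_arm$t <- head_arm$t
  cal2 <- calibrate(rev_arm, head_fore)
  expect_equal(cal1$M1, cal2$M1, tolerance = 1e-12)
})

test_that("a known mounting perturbation is recovered exactly without noise", {
  set.seed(21)
  for (i in 1:5) {
    mounts <- default_mounts()
    mounts$arm <- perturb_mounting(mounts$arm, angle = stats::runif(1, 2, 25))
    s <- static_session(1, mounts = mounts)
    cal <- calibrate(s$arm, s$forearm, mounts = default_mounts())
    A <- cal$M1 %*% default_mounts()$arm$R
    a_raw <- as.numeric(s$arm[1, c("ax", "ay", "az")])
    b_raw <- as.numeric(s$arm[1, c("mx", "my", "mz")])
    expect_equal(as.numeric(A %*% a_raw), anatomical_gravity(),
                 tolerance = 1e-6)
    expect_equal(as.numeric(A %*% b_raw), anatomical_field(),
                 tolerance = 1e-6)
  }
})

test_that("static averaging beats single-sample calibration under noise", {
  # with accelerometer noise, the angular error of the gravity axis shrinks
  # as the static capture grows
  err_for_n <- function(n, seed) {
    set.seed(seed)
    a_true <- anatomical_gravity()
    noisy <- matrix(a_true, n, 3, byrow = TRUE) +
      matrix(stats::rnorm(3 * n, sd = 0.05), n, 3)
    v1 <- colMeans(noisy)
    acos(min(1, sum(v1 * a_true) / sqrt(sum(v1^2)) /
               sqrt(sum(a_true^2)))) * 180 / pi
  }
  wins <- sum(vapply(1:40, function(s) {
    err_for_n(1000, s) < err_for_n(10, s + 1000)
  }, logical(1)))
  expect_gte(wins, 38) # 95 % of trials
})

test_that("degenerate poses raise errors naming the offending sensor", {
  s <- static_session(0.5)
  bad <- s$arm
  bad[, c("mx", "my", "mz")] <- bad[, c("ax", "ay", "az")] * 5
  expect_error(calibrate(bad, s$forearm), "arm")
  expect_error(calibrate(s$arm, bad), "forearm")
})

test_that("mounting rotations recompute from their delta angles", {
  m <- mounting_rotation(1L)
  expect_equal(m$delta, wrap_deg(c(270, 0)))
  expect_equal(m$R, rot_axis("X", 270) %*% rot_axis("Y", 0))
  m2 <- mounting_rotation(2L, c(15, -30))
  expect_equal(m2$R, rot_axis("X", 15) %*% rot_axis("Y", -30))
})

test_that("broom methods summarise a calibration", {
  s <- static_session(1)
  cal <- calibrate(s$arm, s$forearm)
  td <- tidy(cal)
  expect_equal(td$sensor, c("arm", "forearm"))
  expect_equal(td$correction_deg, c(0, 0), tolerance = 1e-7)
  gl <- glance(cal)
  expect_equal(nrow(gl), 1L)
  expect_lt(gl$gravity_residual, 1e-9)
})
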
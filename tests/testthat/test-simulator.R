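test_that("the standard protocol has three five-repetition phases", {
  p <- protocol_standard()
  expect_equal(nrow(p), 3L)
  expect_equal(p$repetitions, rep(5L, 3))
  expect_equal(sum(p$repetitions), 15L)
  expect_equal(p$end_deg[1], 90)
  expect_equal(p$movement[3], "pronation_supination")
  expect_equal(p$pose_mode[3], "elbow_flexed_90")
})

test_that("a static noiseless session has pure gravity and zero rate", {
  s <- static_session(1, rate = 60)
  expect_equal(nrow(s$arm), 60L)
  expect_equal(nrow(s$forearm), 60L)
  norms <- sqrt(s$forearm$ax^2 + s$forearm$ay^2 + s$forearm$az^2)
  expect_equal(norms, rep(9.81, 60), tolerance = 1e-9)
  expect_true(all(abs(s$forearm[, c("gx", "gy", "gz")]) < 1e-9))
  expect_true(all(s$truth$flexion_extension == 0))
})

test_that("a constant-rate flexion ramp shows on the assigned gyro axis in
          the mounted frame", {
  proto <- motion_protocol("flexion_extension", 0, 90, repetitions = 1,
                           period_s = 2, profile = "trapezoid")
  s <- simulate_session(proto, rate = 120, noise = noise_model("none"),
                        t_cal = 1)
  # during the constant-velocity plateau of the first half-repetition the
  # rate is amplitude / (half period * plateau fraction): 90 deg over the
  # shaped half second; the trapezoid's plateau rate is 1/(1-ta) times the
  # mean rate 90/1 s
  plateau <- s$forearm$t > 1.3 & s$forearm$t < 1.7
  expected <- 90 / 1 / (1 - 0.25)
  expect_equal(unname(s$forearm$gz[plateau]),
               rep(expected, sum(plateau)), tolerance = 0.5)
  # forearm mounting is identity, so the sensor z axis is the segment z
  expect_true(all(abs(s$forearm$gx[plateau]) < 1e-6))
  # gyro integral over the outward half equals the commanded 90 degrees
  out_idx <- s$forearm$t >= 1 & s$forearm$t < 2
  expect_equal(sum(s$forearm$gz[out_idx]) / 120, 90, tolerance = 0.1)
})

test_that("the arm-sensor mounting rotation is baked into its raw stream", {
  s <- static_session(0.5)
  # arm sensor mounted 270 degrees about X: raw readings are the anatomical
  # rest vectors carried into the mounted frame
  R1 <- default_mounts()$arm$R
  a_expect <- as.numeric(t(R1) %*% anatomical_gravity())
  expect_equal(as.numeric(s$arm[1, c("ax", "ay", "az")]), a_expect,
               tolerance = 1e-9)
})

test_that("identical seeds give bit-identical streams", {
  s1 <- simulate_session(protocol = NULL, t_cal = 1, seed = 5,
                         noise = noise_model("default"))
  s2 <- simulate_session(protocol = NULL, t_cal = 1, seed = 5,
                         noise = noise_model("default"))
  expect_identical(s1$arm, s2$arm)
  expect_identical(s1$forearm, s2$forearm)
  s3 <- simulate_session(protocol = NULL, t_cal = 1, seed = 6,
                         noise = noise_model("default"))
  expect_false(identical(s1$arm, s3$arm))
})

test_that("truth export sits on the session time base with the commanded
          amplitudes", {
  s <- standard_noiseless()
  tru <- truth_export(s)
  expect_equal(nrow(tru), nrow(s$arm))
  expect_equal(max(tru$flexion_extension[tru$t < 2 + 5 * 2.82]), 90,
               tolerance = 0.5)
  expect_equal(max(tru$flexion_extension), 145, tolerance = 0.5)
  expect_equal(max(abs(tru$pronation_supination)), 80, tolerance = 0.5)
  # session mirrors the reference capture length
  expect_equal(s$duration, 45.3, tolerance = 0.01)
  # static head then three phases plus one transition
  expect_true(all(tru$flexion_extension[tru$t < 2] == 0))
})

test_that("gyro-channel integral of each phase matches its net angle", {
  s <- standard_noiseless()
  dt <- 1 / s$rate
  # phase 1 spans [2, 2 + 5*2.82): net angle zero (out and back), and the
  # half-repetition integral is 90
  idx_half <- s$forearm$t >= 2 & s$forearm$t < 2 + 2.82 / 2
  expect_equal(sum(s$forearm$gz[idx_half]) * dt, 90, tolerance = 0.1)
  idx_phase <- s$forearm$t >= 2 & s$forearm$t < 2 + 5 * 2.82
  expect_equal(sum(s$forearm$gz[idx_phase]) * dt, 0, tolerance = 0.1)
})

test_that("an empty protocol with no calibration segment is rejected", {
  expect_error(simulate_session(protocol = NULL, t_cal = 0), "[Ee]mpty")
})

test_that("noiseless pipeline recovery beats half a degree end to end", {
  s <- standard_noiseless()
  rec <- recover_angles(s)
  tru <- truth_export(s)
  expect_lt(rmse(rec$flexion_extension, tru$flexion_extension), 0.5)
  expect_lt(rmse(rec$pronation_supination, tru$pronation_supination), 0.5)
})

test_that("default-noise pipeline recovery stays under two degrees", {
  s <- standard_noisy(7)
  rec <- recover_angles(s)
  tru <- truth_export(s)
  expect_lt(rmse(rec$flexion_extension, tru$flexion_extension), 2)
  expect_lt(rmse(rec$pronation_supination, tru$pronation_supination), 2)
})
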
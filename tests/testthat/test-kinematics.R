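test_that("low-pass filter matches the analytic two-pass Butterworth response", {
  rate <- 480
  t <- seq(0, 5, by = 1 / rate)
  n <- length(t)
  core <- 500:(n - 500)  # away from filter edge transients
  mk_rec <- function(x) {
    pos <- matrix(0.5, n, 18)
    pos[, 7] <- x  # elbow_x carries the test signal
    marker_recording(t, pos, required_landmarks(), sample_rate = rate)
  }
  # constant channel: DC gain is 1, output identical to numerical precision
  flat <- lowpass_filter(mk_rec(rep(0.3, n)))
  expect_lt(max(abs(flat$positions[, 7] - 0.3)), 1e-6)

  # 1 Hz: amplitude preserved within 1% (analytic |H|^2 at 1 Hz ~ 0.9992)
  s1 <- lowpass_filter(mk_rec(0.5 + 0.1 * sin(2 * pi * 1 * t)))
  amp1 <- max(abs(s1$positions[core, 7] - 0.5))
  expect_gt(amp1 / 0.1, 0.99)

  # 50 Hz: attenuation at least 99% of the analytic two-pass response
  # |H(f)|^2 = 1 / (1 + (f/fc)^4) for a 2nd-order Butterworth, squared pass
  h2_50 <- 1 / (1 + (50 / 6)^4)
  s50 <- lowpass_filter(mk_rec(0.5 + 0.1 * sin(2 * pi * 50 * t)))
  amp50 <- max(abs(s50$positions[core, 7] - 0.5))
  expect_lt(amp50 / 0.1, 1.1 * h2_50)
})

test_that("filter cutoff at or above Nyquist is a parameter error naming both", {
  rec <- hanging_pose(n = 20)
  expect_error(lowpass_filter(rec, cutoff_hz = 15), "15.*[Nn]yquist.*15|Nyquist")
})

test_that("filtering is near-idempotent on signals band-limited below cutoff/2", {
  rate <- 120
  t <- seq(0, 4, by = 1 / rate)
  pos <- matrix(0.5, length(t), 18)
  pos[, 7] <- 0.5 + 0.1 * sin(2 * pi * 2 * t)   # 2 Hz < 6/2 + margin
  rec <- marker_recording(t, pos, required_landmarks(), sample_rate = rate)
  once <- lowpass_filter(rec)
  twice <- lowpass_filter(once)
  core <- 100:(length(t) - 100)
  rel <- max(abs(twice$positions[core, 7] - once$positions[core, 7])) /
    diff(range(once$positions[core, 7]))
  expect_lt(rel, 0.01)
})

test_that("static poses give the textbook joint angles", {
  a <- compute_joint_angles(hanging_pose())
  expect_equal(unname(a$angles[1, "elbow_flexext"]), 180, tolerance = 1e-6)
  expect_equal(unname(a$angles[1, "wrist_flexext"]), 180, tolerance = 1e-6)
  expect_equal(unname(a$angles[1, "shoulder_flexext"]), 0, tolerance = 1e-6)
  expect_equal(unname(a$angles[1, "shoulder_abdadd"]), 0, tolerance = 1e-6)

  b <- compute_joint_angles(right_angle_elbow_pose())
  expect_equal(unname(b$angles[1, "elbow_flexext"]), 90, tolerance = 1e-6)
  expect_equal(unname(b$angles[1, "shoulder_flexext"]), 0, tolerance = 1e-6)
})

test_that("forward kinematics round trip recovers generating angles under 0.5 deg RMS", {
  for (mv in c(1, 4, 10)) {
    s <- generate_movement(mv, sample_rate = 120)
    rec <- landmarks_from_angles(s)
    back <- compute_joint_angles(rec)
    rms <- sqrt(mean((back$angles - s$angles)^2))
    expect_lt(rms, 0.5)
  }
})

test_that("joint angles are invariant to rigid rotation and translation", {
  s <- generate_movement(6, sample_rate = 60)
  rec <- landmarks_from_angles(s)
  a0 <- compute_joint_angles(rec)

  set.seed(7)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  R <- Rz %*% Rx
  shift <- c(1.2, -0.4, 2.0)
  rot <- rec
  for (i in seq(1, 18, by = 3)) {
    rot$positions[, i:(i + 2)] <-
      sweep(rec$positions[, i:(i + 2)] %*% t(R), 2, shift, `+`)
  }
  a1 <- compute_joint_angles(rot)
  expect_angles_equal(a0, a1, tol = 1e-6)
})

test_that("degenerate poses are flagged and excess degeneracy invalidates the trial", {
  rec <- hanging_pose(n = 20)
  # collapse wrist onto elbow for 1 sample: wrist angle undefined there
  rec$positions[5, 10:12] <- rec$positions[5, 7:9]
  a <- compute_joint_angles(rec)
  expect_equal(attr(a, "degenerate"), 5L)
  expect_false(anyNA(a$angles))

  rec2 <- hanging_pose(n = 20)
  rec2$positions[1:10, 10:12] <- rec2$positions[1:10, 7:9]
  expect_error(compute_joint_angles(rec2), "invalid")
})

test_that("resampling preserves linear ramps, endpoints, and identity length", {
  ramp <- joint_angle_series(
    cbind(seq(0, 90, length.out = 300), seq(0, 45, length.out = 300),
          seq(90, 180, length.out = 300), seq(100, 150, length.out = 300)),
    sample_rate = 30)
  r <- resample_series(ramp, 100)
  expect_equal(nrow(r$angles), 100)
  expect_equal(r$angles[1, ], ramp$angles[1, ], tolerance = 1e-9)
  expect_equal(r$angles[100, ], ramp$angles[300, ], tolerance = 1e-9)
  expect_lt(max(abs(diff(diff(r$angles[, 1])))), 1e-9)  # still exactly linear

  ident <- resample_series(ramp, 300)
  expect_angles_equal(ident, ramp, tol = 1e-9)

  expect_error(resample_series(ramp, 1), "n_points")
})

test_that("480 Hz and 30 Hz renderings of one trajectory agree after resampling", {
  s480 <- generate_movement(2, sample_rate = 480)
  s30 <- generate_movement(2, sample_rate = 30)
  a <- resample_series(s480, 100)
  b <- resample_series(s30, 100)
  expect_lt(sqrt(mean((a$angles - b$angles)^2)), 0.5)
})
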
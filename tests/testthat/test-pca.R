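test_that("a rank-1 movement yields a single component explaining everything", {
  t <- seq(0, 1, length.out = 100)
  d <- sin(pi * t)
  ang <- cbind(30 * d, 10 * d, 120 - 40 * d, 150 - 20 * d)
  s <- joint_angle_series(ang + rep(c(10, 10, 0, 0), each = 100) * 0, 100)
  b <- derive_basis(s)
  expect_equal(b$var_fractions[1], 1, tolerance = 1e-12)
  expect_equal(b$k, 1L)
})

test_that("two orthogonal equal-variance patterns give two equal leading eigenvalues and k = 2", {
  t <- (0:199) / 200                # one exact period: sums are exact
  d1 <- sqrt(2) * sin(2 * pi * t)
  d2 <- sqrt(2) * cos(2 * pi * t)   # equal variance, orthogonal in time
  a1 <- c(1, 1, 1, 1) / 2
  a2 <- c(1, -1, 1, -1) / 2         # orthonormal joint patterns
  ang <- 10 * (outer(d1, a1) + outer(d2, a2)) +
    matrix(c(30, 30, 120, 120), 200, 4, byrow = TRUE)
  b <- derive_basis(joint_angle_series(ang, 100))
  expect_equal(b$eigenvalues[1], b$eigenvalues[2], tolerance = 1e-9)
  expect_equal(b$eigenvalues[3], 0, tolerance = 1e-9)
  expect_equal(b$k, 2L)
})

test_that("basis eigendecomposition matches an independent SVD oracle", {
  # oracle: singular values of the demeaned matrix, squared / (n-1)
  for (seed in 1:20) {
    s <- random_trial(r = 4, seed = seed)
    b <- derive_basis(s)
    Xc <- sweep(s$angles, 2, colMeans(s$angles))
    sv <- svd(Xc)
    expect_equal(b$eigenvalues, sv$d^2 / (nrow(Xc) - 1), tolerance = 1e-10)
    for (j in 1:4) {
      expect_equal(abs(sum(b$loadings[, j] * sv$v[, j])), 1, tolerance = 1e-8)
    }
    expect_equal(crossprod(b$loadings), diag(4), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(sum(b$var_fractions), 1, tolerance = 1e-12)
    expect_true(all(diff(b$eigenvalues) <= 1e-12))
  }
})

test_that("a constant channel is valid (zero eigenvalue) but all-constant input errors", {
  t <- seq(0, 1, length.out = 50)
  ang <- cbind(20 * sin(pi * t), rep(5, 50), 120 + 10 * t, rep(150, 50))
  b <- derive_basis(joint_angle_series(ang, 49))
  expect_equal(min(b$eigenvalues), 0, tolerance = 1e-9)

  flat <- joint_angle_series(matrix(rep(c(10, 5, 120, 150), each = 50), 50), 49)
  expect_error(derive_basis(flat), "degenerate|constant")
})

test_that("reconstruction identities hold: span, complete basis, orthogonal trial", {
  base <- random_trial(r = 2, seed = 4)
  b <- derive_basis(base, variance_threshold = 0.999)
  expect_equal(b$k, 2L)

  # trial within the span of the retained loadings reconstructs exactly
  rec <- reconstruct(base, b)
  expect_angles_equal(rec, base, tol = 1e-8)
  expect_equal(score_trial(base, b)$value, 1, tolerance = 1e-10)

  # complete basis reconstructs anything exactly
  b4 <- derive_basis(base, variance_threshold = 1)
  expect_equal(b4$k, 4L)
  any_trial <- random_trial(r = 4, seed = 5)
  expect_angles_equal(reconstruct(any_trial, b4), any_trial, tol = 1e-8)
  expect_equal(score_trial(any_trial, b4)$value, 1, tolerance = 1e-10)

  # trial orthogonal (in demeaned joint space) to retained loadings
  # reconstructs to its flat mean trace and scores 0
  V <- b$loadings[, 1:2]
  perp <- b$loadings[, 3]
  t <- seq(0, 1, length.out = 100)
  ang <- outer(20 * sin(2 * pi * t), perp) +
    matrix(c(30, 30, 120, 120), 100, 4, byrow = TRUE)
  ortho <- joint_angle_series(ang, 99)
  rec2 <- reconstruct(ortho, b)
  expect_lt(max(abs(sweep(rec2$angles, 2, colMeans(ortho$angles)))), 1e-8)
  expect_equal(score_trial(ortho, b)$value, 0, tolerance = 1e-10)
})

test_that("the basis-source mean trace scores its retained cumulative variance fraction", {
  for (seed in c(6, 7, 8)) {
    s <- random_trial(r = 4, seed = seed)
    b <- derive_basis(s, variance_threshold = 0.95)
    sc <- score_trial(s, b)
    expect_equal(sc$value, sum(b$var_fractions[seq_len(b$k)]),
                 tolerance = 1e-10)
  }
})

test_that("scores are bias-immune and never exceed 1; zero-variance trials are flagged", {
  s <- random_trial(r = 3, seed = 9)
  b <- derive_basis(s)
  sc0 <- score_trial(s, b)$value
  biased <- s
  biased$angles <- sweep(s$angles, 2, c(26, -16, 20, 25), `+`)
  expect_lt(abs(score_trial(biased, b)$value - sc0), 1e-10)
  expect_lte(sc0, 1)

  flat <- joint_angle_series(matrix(rep(c(10, 5, 120, 150), each = 50), 50), 49)
  sc <- score_trial(flat, b)
  expect_false(sc$valid)
  expect_true(is.na(sc$value))
})

test_that("per-channel pooling can go negative and is preserved unclipped", {
  base <- random_trial(r = 2, seed = 10)
  b <- derive_basis(base, variance_threshold = 0.999)
  # trial pattern w = (out-of-span direction) + alpha * (retained loading),
  # with alpha cancelling most of one channel: that channel keeps almost no
  # variance but receives the full residual -> strongly negative R^2 there
  v <- b$loadings[, 4]
  V1 <- b$loadings[, 1]
  j <- which.max(abs(v * V1))
  w <- v - 0.95 * (v[j] / V1[j]) * V1
  t <- seq(0, 1, length.out = 100)
  ang <- outer(5 * sin(2 * pi * t), w) +
    matrix(c(30, 30, 90, 90), 100, 4, byrow = TRUE)
  tr <- joint_angle_series(ang, 99)
  sc <- score_trial(tr, b, pooling = "per_channel")
  expect_lt(sc$value, 0)
})

test_that("baseline scoring returns one score per trial and supports leave-one-out", {
  reps <- lapply(1:5, function(i) {
    s <- generate_movement(3, sample_rate = 30, amp_jitter = 0.05,
                           motor_noise_sd = 0.5, seed = 100 + i)
    resample_series(s, 100)
  })
  trials <- segmented_trials(reps, 1:5)
  basis <- derive_basis(align_and_average(trials))
  bl <- score_baseline(trials, basis)
  expect_equal(nrow(bl), 5)
  expect_true(all(bl$value <= 1 + 1e-12))

  loo <- score_baseline(trials, basis, mode = "leave_one_out")
  expect_equal(nrow(loo), 5)
  # leave-one-out cannot use the trial itself, so scores differ
  expect_false(isTRUE(all.equal(bl$value, loo$value)))

  # noise-free identical repetitions: all baseline scores equal
  same <- segmented_trials(rep(list(reps[[1]]), 3), 1:3)
  b2 <- derive_basis(align_and_average(same))
  bl2 <- score_baseline(same, b2)
  expect_equal(diff(range(bl2$value)), 0, tolerance = 1e-12)
})

test_that("scores degrade monotonically with abnormal-coupling magnitude at fixed noise", {
  base_trials <- lapply(1:10, function(i) {
    resample_series(generate_movement(4, sample_rate = 60, amp_jitter = 0.05,
                                      motor_noise_sd = 0.5, seed = 200 + i), 100)
  })
  basis <- derive_basis(align_and_average(segmented_trials(base_trials, 1:10)))
  set.seed(31)
  means <- sapply(c(0, 0.2, 0.4), function(g) {
    mean(replicate(100, {
      tr <- generate_movement(4, sample_rate = 60, amp_jitter = 0.05,
                              motor_noise_sd = 0.5)
      p <- impairment_params(0.5, excursion_scale = 1, coupling_gain = g,
                             tremor_sd = 1, slowing = 1)
      score_trial(resample_series(apply_impairment(tr, p), 100), basis)$value
    }))
  })
  expect_true(all(diff(means) < 0))
})
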
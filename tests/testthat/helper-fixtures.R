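# Shared fixture builders: everything is generated in code at test time.

# Static arm pose -> one-sample landmark recording replicated n times.
# Canonical trunk: pelvis at origin, shoulders on the x axis, z up, y forward.
pose_recording <- function(elbow, wrist, hand, n = 3, rate = 30) {
  g <- arm_geometry()
  S <- c(g$shoulder_width / 2, 0, g$trunk_height)
  C <- c(-g$shoulder_width / 2, 0, g$trunk_height)
  P <- c(0, 0, 0)
  pos <- matrix(rep(c(S, C, elbow, wrist, hand, P), each = n), nrow = n)
  marker_recording(time = (seq_len(n) - 1) / rate, positions = pos,
                   labels = required_landmarks(), sample_rate = rate)
}

# Arm hanging straight down, fully extended.
hanging_pose <- function(n = 3) {
  g <- arm_geometry()
  S <- c(g$shoulder_width / 2, 0, g$trunk_height)
  E <- S - c(0, 0, g$upper)
  W <- E - c(0, 0, g$forearm)
  H <- W - c(0, 0, g$hand)
  pose_recording(E, W, H, n = n)
}

# Upper arm hanging, forearm at a right angle pointing forward (sagittal).
right_angle_elbow_pose <- function(n = 3) {
  g <- arm_geometry()
  S <- c(g$shoulder_width / 2, 0, g$trunk_height)
  E <- S - c(0, 0, g$upper)
  W <- E + c(0, g$forearm, 0)
  H <- W + c(0, g$hand, 0)
  pose_recording(E, W, H, n = n)
}

# Write a minimal tabular marker file by hand (to exercise the parser
# independently of write_marker_file).
write_raw_marker_file <- function(path, time, cols, labels,
                                  meta = character(0)) {
  hdr <- c("time", as.vector(t(outer(labels, c("x", "y", "z"), paste, sep = "_"))))
  rows <- apply(cbind(time, cols), 1, paste, collapse = "\t")
  writeLines(c(meta, paste(hdr, collapse = "\t"), rows), path)
  path
}

# Random smooth 100-point trial from a random rank-<=r joint pattern.
random_trial <- function(r = 3, n = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, 1, length.out = n)
  drives <- sapply(seq_len(r), function(i) sin(pi * i * t + stats::runif(1, 0, pi)))
  A <- matrix(stats::rnorm(4 * r, 0, 10), 4, r)
  ang <- drives %*% t(A) + matrix(c(20, 20, 120, 120), n, 4, byrow = TRUE)
  ang[, 3:4] <- pmin(pmax(ang[, 3:4], 0), 180)
  joint_angle_series(ang, sample_rate = (n - 1) / 1)
}

expect_angles_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a$angles - b$angles)), tol)
}

# Fixture: a continuous series holding n_reps copies of a movement with
# resting gaps, with the true onset indices and the matched template.
concat_session <- function(mv = 2, n_reps = 3, rate = 30, gap_s = 1,
                           noise_sd = 0, seed = 1) {
  set.seed(seed)
  rep_s <- generate_movement(mv, sample_rate = rate)
  rest <- matrix(movement_model(mv)$rest, round(gap_s * rate), 4, byrow = TRUE)
  pieces <- list(rest)
  onsets <- integer(n_reps)
  cursor <- nrow(rest)
  for (i in seq_len(n_reps)) {
    onsets[i] <- cursor + 1L
    pieces[[length(pieces) + 1]] <- rep_s$angles
    pieces[[length(pieces) + 1]] <- rest
    cursor <- cursor + nrow(rep_s$angles) + nrow(rest)
  }
  ang <- do.call(rbind, pieces)
  if (noise_sd > 0) ang <- ang + matrix(rnorm(length(ang), 0, noise_sd), nrow(ang))
  ang[, 3:4] <- pmin(pmax(ang[, 3:4], 0), 180)
  list(series = joint_angle_series(ang, sample_rate = rate),
       template = movement_template(rep_s$angles, mv, rate),
       onsets = onsets)
}
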
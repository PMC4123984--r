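# Synthetic ground truth for the whole pipeline: smooth multi-joint
# movements driven by <= 2 latent minimum-jerk drives (so a 2-component
# basis explains 100% of a noise-free movement), paretic-side impairment
# operators (reduced excursion, abnormal inter-joint coupling, tremor-band
# noise, slowing), capture models for a high-rate standard system and a
# bias-dominated low-cost system, and noisy ordinal rater panels.

#' Minimum-jerk position profile
#'
#' The classic smooth point-to-point profile `10 t^3 - 15 t^4 + 6 t^5` on
#' normalized time `t` in [0, 1]; its velocity peaks at mid-movement and is
#' symmetric.
#' @param t normalized time in [0, 1] (values outside are clamped).
#' @export
minimum_jerk <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  10 * t^3 - 15 * t^4 + 6 * t^5
}

# Out-and-back drive: rises by minimum jerk, returns by its mirror.
drive_out_back <- function(tau) {
  ifelse(tau <= 0.5, minimum_jerk(2 * tau), minimum_jerk(2 - 2 * tau))
}

# Second latent drive: the normalized time-derivative of the out-and-back
# profile — biphasic, zero at both ends, and orthogonal in time to the
# symmetric first drive (a transient acceleration/overshoot component).
drive_transient <- function(tau) {
  d1 <- drive_out_back(tau)
  n <- length(tau)
  g <- c(d1[2] - d1[1], (d1[3:n] - d1[1:(n - 2)]) / 2, d1[n] - d1[n - 1])
  m <- max(abs(g))
  if (m > 0) g / m else g
}

#' Built-in movement model presets
#'
#' Ten upper-limb movement models mirroring the structure of item-level
#' clinical test movements (which joints move and in which direction),
#' without claiming biomechanical fidelity. Each model holds a resting
#' posture, a 4 x 2 synergy matrix coupling the four joints to two latent
#' minimum-jerk drives (amplitudes in degrees embedded in the matrix), a
#' phase offset of the second drive, and a duration.
#' @return named list of 10 movement models.
#' @export
movement_presets <- function() {
  rest <- c(10, 8, 150, 165)
  W <- function(...) matrix(c(...), nrow = 4)
  mk <- function(name, W, duration, phase = 0) {
    list(name = name, rest = rest, synergy = W,
         duration = duration, phase = phase)
  }
  list(
    `1` = mk("hand_to_lumbar_spine", W(-30, 5, -60, -10,   -8, 3, 25, -6), 1.8),
    `2` = mk("shoulder_flexion_90",  W(60, 5, 0, 0,        12, 3, 14, 0), 1.6),
    `3` = mk("shoulder_abduction",   W(5, 55, 0, 0,        3, 12, 14, 6), 1.6),
    `4` = mk("hand_to_mouth",        W(25, 5, -80, -15,    10, 3, 28, -10), 1.5),
    `5` = mk("reach_forward",        W(45, 10, 20, 5,      -10, 6, 14, 4), 1.4),
    `6` = mk("arm_raise_diagonal",   W(40, 40, 10, 0,      8, 8, -16, 4), 1.8, 0.1),
    `7` = mk("elbow_flexion",        W(5, 0, -70, 0,       1, 0, -4, 3), 1.2),
    `8` = mk("wrist_flexion",        W(0, 0, -10, -60,     0, 3, -20, 6), 1.2),
    `9` = mk("drinking",             W(30, 10, -60, -30,   12, 4, 16, -18), 2.0, 0.1),
    `10` = mk("reach_to_side",       W(10, 45, 25, 5,      14, -8, 10, 4), 1.5)
  )
}

#' Fetch one movement model
#' @param movement_type preset number 1-10, or a model list built by hand
#'   with fields `rest`, `synergy` (4 x 2), `duration`, `phase`.
#' @export
movement_model <- function(movement_type) {
  if (is.list(movement_type)) return(movement_type)
  m <- movement_presets()[[as.character(movement_type)]]
  if (is.null(m)) stop(sprintf("no movement preset '%s'", as.character(movement_type)))
  m$type <- movement_type
  m
}

# Smooth low-frequency noise with per-channel s.d. `sd` (degrees).
smooth_noise <- function(n, sd, sample_rate, cutoff = 2) {
  if (sd <= 0) return(matrix(0, n, 4))
  noise <- matrix(stats::rnorm(n * 4), n, 4)
  if (cutoff < sample_rate / 2 && n > 12) {
    bf <- signal::butter(2, cutoff / (sample_rate / 2), type = "low")
    pad <- ceiling(3 * sample_rate / cutoff)
    noise <- apply(noise, 2, function(x) zero_phase_filter(x, bf, pad))
  }
  apply(noise, 2, function(x) {
    s <- stats::sd(x)
    if (s > 0) x / s * sd else x
  })
}

#' Generate one noise-controlled movement repetition
#'
#' Latent drives follow out-and-back minimum-jerk profiles (the movement
#' returns to the resting posture); joint angles are the synergy matrix
#' times the drives plus the resting posture. Optional trial-to-trial motor
#' variability: multiplicative amplitude jitter on each synergy column and
#' additive smooth (low-frequency) noise.
#'
#' @param model a movement model (preset number or list, see
#'   [movement_model()]).
#' @param sample_rate output rate in Hz (default 480, the standard system).
#' @param amp_jitter s.d. of the multiplicative amplitude jitter
#'   (default 0 = none).
#' @param motor_noise_sd s.d. in degrees of additive smooth noise
#'   (default 0 = none).
#' @param seed RNG seed.
#' @param limb_side,system_tag metadata for the output series.
#' @return a [joint_angle_series()].
#' @export
generate_movement <- function(model, sample_rate = 480, amp_jitter = 0,
                              motor_noise_sd = 0, seed = NULL,
                              limb_side = "left", system_tag = "truth") {
  model <- movement_model(model)
  if (model$duration <= 0) stop("movement duration must be positive")
  with_seed(seed, {
    n <- round(model$duration * sample_rate) + 1
    tau <- seq(0, 1, length.out = n)
    d1 <- drive_out_back(tau)
    tau2 <- pmin(pmax((tau - model$phase) / (1 - model$phase), 0), 1)
    d2 <- drive_transient(tau2)
    W <- model$synergy
    if (amp_jitter > 0) {
      W <- W * matrix(stats::rnorm(2, 1, amp_jitter), nrow = 4, ncol = 2,
                      byrow = TRUE)
    }
    ang <- cbind(d1, d2) %*% t(W)
    ang <- sweep(ang, 2, model$rest, `+`)
    ang <- ang + smooth_noise(n, motor_noise_sd, sample_rate)
    ang[, 3:4] <- pmin(pmax(ang[, 3:4], 0), 180)
    joint_angle_series(ang, sample_rate = sample_rate, limb_side = limb_side,
                       system_tag = system_tag,
                       provenance = sprintf("synthetic:%s", model$name))
  })
}

#' Impairment parameter set
#'
#' Kinematic signatures of hemiparesis as a function of a single severity
#' `s` in [0, 1]: excursion reduced to `1 - 0.5 s` of normal, abnormal
#' inter-joint coupling (a fraction `0.4 s` of each joint's demeaned drive
#' leaks in from a neighbouring joint), band-limited 3-6 Hz tremor of s.d.
#' `2.5 s` degrees, and slowing by a factor `1 + s`. At `s = 0` every
#' operator is the identity.
#'
#' @param severity s in [0, 1].
#' @param excursion_scale,coupling_gain,tremor_sd,slowing override the
#'   default severity scalings.
#' @export
impairment_params <- function(severity,
                              excursion_scale = 1 - 0.5 * severity,
                              coupling_gain = 0.4 * severity,
                              tremor_sd = 2.5 * severity,
                              slowing = 1 + severity) {
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  list(severity = severity, excursion_scale = excursion_scale,
       coupling_gain = coupling_gain, tremor_sd = tremor_sd,
       slowing = slowing)
}

#' Apply paretic-side impairment to a movement
#'
#' Operators, in order: time dilation by the slowing factor; coupling
#' leakage mixing each joint's demeaned trace with its neighbour's;
#' channel-wise rescaling so every joint's excursion equals
#' `excursion_scale` times the input's excursion (exact by construction);
#' additive band-limited (3-6 Hz) tremor noise. `severity = 0` returns the
#' input unchanged.
#'
#' @param series a [joint_angle_series()].
#' @param params an [impairment_params()] (or a bare severity value).
#' @param seed RNG seed (used by the tremor noise).
#' @return impaired [joint_angle_series()].
#' @export
apply_impairment <- function(series, params, seed = NULL) {
  if (is.numeric(params)) params <- impairment_params(params)
  X <- series$angles
  n <- nrow(X)
  target_exc <- apply(X, 2, function(x) diff(range(x))) * params$excursion_scale

  if (params$slowing != 1) {
    n2 <- round((n - 1) * params$slowing) + 1
    idx <- seq(1, n, length.out = n2)
    X <- apply(X, 2, function(x) stats::approx(seq_len(n), x, xout = idx)$y)
    n <- n2
  }
  g <- params$coupling_gain
  if (g > 0 || params$excursion_scale != 1) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    if (g > 0) {
      Xc <- (1 - g) * Xc + g * Xc[, c(2, 3, 4, 1)]
    }
    cur_exc <- apply(Xc, 2, function(x) diff(range(x)))
    scale <- ifelse(cur_exc > 1e-12, target_exc / cur_exc, 1)
    Xc <- sweep(Xc, 2, scale, `*`)
    X <- sweep(Xc, 2, mu, `+`)
  }
  if (params$tremor_sd > 0) {
    X <- X + with_seed(seed, tremor_noise(n, params$tremor_sd, series$sample_rate))
  }
  X[, 3:4] <- pmin(pmax(X[, 3:4], 0), 180)
  X[, 1:2] <- pmin(pmax(X[, 1:2], -180), 180)
  out <- series
  out$angles <- X
  out$provenance <- sprintf("%s|severity=%.2f", series$provenance, params$severity)
  validate_joint_angle_series(out)
}

# Band-limited (3-6 Hz) noise, per-channel s.d. = sd degrees. Falls back to
# white noise when the sample rate cannot represent the band.
tremor_noise <- function(n, sd, sample_rate) {
  noise <- matrix(stats::rnorm(n * 4), n, 4)
  nyq <- sample_rate / 2
  if (nyq > 6.5 && n > 18) {
    bf <- signal::butter(2, c(3, 6) / nyq, type = "pass")
    pad <- ceiling(sample_rate)
    noise <- apply(noise, 2, function(x) zero_phase_filter(x, bf, pad))
  }
  apply(noise, 2, function(x) {
    s <- stats::sd(x)
    if (s > 0) x / s * sd else x
  })
}

#' Arm segment geometry used by the forward kinematics
#' @param upper,forearm,hand segment lengths in meters.
#' @param shoulder_width,trunk_height trunk dimensions in meters.
#' @export
arm_geometry <- function(upper = 0.30, forearm = 0.26, hand = 0.08,
                         shoulder_width = 0.35, trunk_height = 0.50) {
  list(upper = upper, forearm = forearm, hand = hand,
       shoulder_width = shoulder_width, trunk_height = trunk_height)
}

# Unit vector perpendicular to each row of d, built from a fixed reference
# axis (anteroposterior, falling back to mediolateral near parallelism).
row_perp <- function(d, ref1 = c(0, 1, 0), ref2 = c(1, 0, 0)) {
  p <- row_cross(d, matrix(ref1, nrow(d), 3, byrow = TRUE))
  nn <- row_norm(p)
  bad <- nn < 1e-8
  if (any(bad)) {
    p2 <- row_cross(d[bad, , drop = FALSE],
                    matrix(ref2, sum(bad), 3, byrow = TRUE))
    p[bad, ] <- p2
    nn[bad] <- row_norm(p2)
  }
  p / pmax(nn, 1e-12)
}

#' Forward kinematics: landmark trajectories from joint angles
#'
#' Places the trunk in a canonical upright pose (pelvis at the origin,
#' shoulders on the mediolateral axis) and reconstructs elbow, wrist and
#' hand landmark positions realizing the four joint angles. Inverse of
#' [compute_joint_angles()] for shoulder angles within (-90, 90) degrees
#' (beyond, the two projected shoulder angles are not uniquely invertible).
#'
#' @param series a [joint_angle_series()].
#' @param geometry an [arm_geometry()].
#' @return a [marker_recording()] with the required landmark set.
#' @export
landmarks_from_angles <- function(series, geometry = arm_geometry()) {
  ang <- series$angles * pi / 180
  if (any(abs(series$angles[, 1:2]) >= 90)) {
    stop("forward kinematics requires shoulder angles within (-90, 90) degrees")
  }
  n <- nrow(ang)
  g <- geometry
  P <- matrix(0, n, 3)
  mid <- matrix(c(0, 0, g$trunk_height), n, 3, byrow = TRUE)
  S <- mid; S[, 1] <- S[, 1] + g$shoulder_width / 2
  C <- mid; C[, 1] <- C[, 1] - g$shoulder_width / 2

  # upper-arm direction from the two projected shoulder angles:
  # components (mediolateral, anteroposterior, vertical) ~ (tan sa, tan sf, -1)
  d <- row_unit(cbind(tan(ang[, 2]), tan(ang[, 1]), -1))
  E <- S + g$upper * d
  p <- row_perp(d)
  f <- -cos(ang[, 3]) * d + sin(ang[, 3]) * p
  W <- E + g$forearm * f
  q <- row_perp(f)
  h <- -cos(ang[, 4]) * f + sin(ang[, 4]) * q
  H <- W + g$hand * h

  pos <- cbind(S, C, E, W, H, P)
  marker_recording(
    time = (seq_len(n) - 1) / series$sample_rate,
    positions = pos,
    labels = required_landmarks(),
    sample_rate = series$sample_rate,
    limb_side = series$limb_side,
    system_tag = if (series$system_tag == "truth") "standard" else series$system_tag,
    session_id = series$provenance
  )
}

#' Capture model for a motion-capture system
#'
#' Noise/bias structure of a capture system in angle and landmark space:
#' a per-channel additive angular bias (degrees, drawn once per trial —
#' the signature of consistently misidentified tracked points), white
#' angular noise per sample, and landmark-level positional noise. The
#' low-cost defaults are bias-dominated and produce per-channel angular RMS
#' errors against truth in the 16-26 degree band.
#'
#' @param system_tag `"standard"` (480 Hz, near-transparent) or
#'   `"lowcost"` (30 Hz, bias-dominated).
#' @param sample_rate,bias_sd,noise_sd,pos_noise_m override the defaults.
#' @export
capture_model <- function(system_tag = c("standard", "lowcost"),
                          sample_rate = NULL, bias_sd = NULL, noise_sd = NULL,
                          pos_noise_m = NULL) {
  system_tag <- match.arg(system_tag)
  def <- if (system_tag == "standard") {
    list(sample_rate = 480, bias_sd = 1, noise_sd = 0.5, pos_noise_m = 0.001)
  } else {
    list(sample_rate = 30, bias_sd = 25, noise_sd = 3, pos_noise_m = 0.004)
  }
  list(system_tag = system_tag,
       sample_rate = if (is.null(sample_rate)) def$sample_rate else sample_rate,
       bias_sd = if (is.null(bias_sd)) def$bias_sd else bias_sd,
       noise_sd = if (is.null(noise_sd)) def$noise_sd else noise_sd,
       pos_noise_m = if (is.null(pos_noise_m)) def$pos_noise_m else pos_noise_m)
}

#' Simulate motion capture of a true movement
#'
#' Resamples the true angle trajectories to the system rate, injects the
#' per-trial angular bias and per-sample angular noise, converts to
#' landmark trajectories by forward kinematics, and adds positional noise.
#' Up to that noise, [compute_joint_angles()] inverts this operation.
#' Biased shoulder angles are clamped to +/- 85 degrees (elbow/wrist to
#' [5, 175]) to stay within the invertible range of the forward kinematics.
#'
#' @param truth a [joint_angle_series()] (the noise-free trajectory).
#' @param cap a [capture_model()].
#' @param seed RNG seed.
#' @return a [marker_recording()] at the system's rate.
#' @export
simulate_capture <- function(truth, cap, seed = NULL) {
  with_seed(seed, {
    dur <- (n_samples(truth) - 1) / truth$sample_rate
    n_cap <- max(2, round(dur * cap$sample_rate) + 1)
    s <- resample_series(truth, n_cap)
    bias <- stats::rnorm(4, 0, cap$bias_sd)
    ang <- sweep(s$angles, 2, bias, `+`) +
      matrix(stats::rnorm(n_cap * 4, 0, cap$noise_sd), n_cap, 4)
    ang[, 1:2] <- pmin(pmax(ang[, 1:2], -85), 85)
    ang[, 3:4] <- pmin(pmax(ang[, 3:4], 5), 175)
    s$angles <- ang
    s$system_tag <- cap$system_tag
    rec <- landmarks_from_angles(s)
    rec$positions <- rec$positions +
      matrix(stats::rnorm(length(rec$positions), 0, cap$pos_noise_m),
             nrow(rec$positions))
    rec$system_tag <- cap$system_tag
    rec
  })
}

#' Simulate a panel of noisy ordinal raters
#'
#' Each rater's score of an item is `scale_max * quality` plus Gaussian
#' noise, rounded and clipped to {0..scale_max} — the generative model of
#' an imperfect clinical rater on the 3-point impairment scale.
#'
#' @param items data.frame with columns `participant`, `movement`, `limb`,
#'   `quality` (true movement quality in [0, 1]).
#' @param n_raters number of raters.
#' @param rater_noise s.d. of the pre-rounding rater noise, in score units
#'   (default 0.35).
#' @param scale_max maximal score (default 2).
#' @param seed RNG seed.
#' @return a [rating_panel()].
#' @export
simulate_raters <- function(items, n_raters, rater_noise = 0.35,
                            scale_max = 2, seed = NULL) {
  if (n_raters < 1) stop("at least one rater is required")
  with_seed(seed, {
    reps <- items[rep(seq_len(nrow(items)), each = n_raters),
                  c("participant", "movement", "limb"), drop = FALSE]
    reps$rater <- rep(sprintf("rater%02d", seq_len(n_raters)), nrow(items))
    raw <- scale_max * rep(items$quality, each = n_raters) +
      stats::rnorm(nrow(reps), 0, rater_noise)
    reps$score <- pmin(pmax(round(raw), 0), scale_max)
    rownames(reps) <- NULL
    rating_panel(reps, scale_max = scale_max)
  })
}

#' Simulate a continuous recording session of repeated movements
#'
#' Generates `n_reps` repetitions of one movement (with trial-to-trial
#' motor variability and, for a paretic limb, the impairment operators),
#' concatenated with resting holds, and optionally captures the session
#' with a [capture_model()] (the angular bias is drawn once per session, as
#' a fixed landmark misidentification would produce).
#'
#' @param model movement model or preset number.
#' @param n_reps number of repetitions.
#' @param severity impairment severity in [0, 1] (0 = unimpaired).
#' @param cap a [capture_model()] or `NULL` for the noise-free truth only.
#' @param gap_s resting-hold duration between repetitions (s).
#' @param truth_rate ground-truth sample rate (Hz).
#' @param amp_jitter,motor_noise_sd trial-to-trial motor variability
#'   (see [generate_movement()]).
#' @param limb_side limb label.
#' @param seed RNG seed.
#' @return list: `truth` ([joint_angle_series()]), `recording`
#'   ([marker_recording()] or `NULL`), `onsets` (truth sample indices),
#'   `rep_samples` (repetition length in truth samples), and the equivalents
#'   on the capture time base (`onsets_capture`, `rep_samples_capture`).
#' @export
simulate_session <- function(model, n_reps, severity = 0, cap = NULL,
                             gap_s = 0.8, truth_rate = 120,
                             amp_jitter = 0.05, motor_noise_sd = 0.5,
                             limb_side = "left", seed = NULL) {
  model <- movement_model(model)
  with_seed(seed, {
    params <- impairment_params(severity)
    reps <- lapply(seq_len(n_reps), function(i) {
      r <- generate_movement(model, sample_rate = truth_rate,
                             amp_jitter = amp_jitter,
                             motor_noise_sd = motor_noise_sd,
                             limb_side = limb_side)
      if (severity > 0) r <- apply_impairment(r, params)
      r
    })
    rep_n <- n_samples(reps[[1]])
    gap_n <- round(gap_s * truth_rate)
    rest_block <- function(n) {
      matrix(model$rest, n, 4, byrow = TRUE) +
        smooth_noise(n, 0.3 * (1 + motor_noise_sd), truth_rate)
    }
    pieces <- list(rest_block(gap_n))
    onsets <- integer(n_reps)
    cursor <- gap_n
    for (i in seq_len(n_reps)) {
      onsets[i] <- cursor + 1L
      pieces[[length(pieces) + 1]] <- reps[[i]]$angles
      cursor <- cursor + n_samples(reps[[i]])
      pieces[[length(pieces) + 1]] <- rest_block(gap_n)
      cursor <- cursor + gap_n
    }
    ang <- do.call(rbind, pieces)
    ang[, 3:4] <- pmin(pmax(ang[, 3:4], 0), 180)
    truth <- joint_angle_series(ang, sample_rate = truth_rate,
                                limb_side = limb_side, system_tag = "truth",
                                provenance = sprintf("session:%s:s=%.2f",
                                                     model$name, severity))
    recording <- NULL
    onsets_cap <- rep_cap <- NULL
    if (!is.null(cap)) {
      recording <- simulate_capture(truth, cap)
      ratio <- recording$sample_rate / truth_rate
      onsets_cap <- pmax(1L, round((onsets - 1) * ratio) + 1L)
      rep_cap <- max(2L, round(n_samples(reps[[1]]) * ratio))
    }
    list(truth = truth, recording = recording, onsets = onsets,
         rep_samples = rep_n, onsets_capture = onsets_cap,
         rep_samples_capture = rep_cap, severity = severity)
  })
}

#' Simulate and score a full synthetic study
#'
#' The end-to-end benchmark: participants with severities spread over the
#' impairment range perform every movement with both limbs (non-paretic at
#' severity 0, paretic at the participant's severity). Each session is
#' captured, low-pass filtered, converted to joint angles, segmented by
#' template correlation (template built from the session's marked onsets —
#' the manual-marking analog), and scored: the principal components of the
#' averaged non-paretic movement reconstruct paretic single trials. A
#' 30-rater panel scores the paretic movements on the ordinal scale.
#'
#' @param n_participants,n_movements,n_reps study dimensions
#'   (defaults 8, 10, 10).
#' @param severities per-participant severities; default spread over
#'   [0.1, 0.9].
#' @param systems character vector of capture systems to run
#'   (`"lowcost"`, `"standard"`), or `"truth"` for noise-free angles.
#' @param n_raters raters in the simulated panel (default 30).
#' @param rater_noise rater noise s.d. in score units.
#' @param seed RNG seed (one seed drives the whole study).
#' @param ... passed to [simulate_session()] (`truth_rate`, `gap_s`,
#'   `amp_jitter`, `motor_noise_sd`).
#' @return list of class `impairment_study`: `scores` (data.frame:
#'   participant, movement, system, limb, trial, k, score), `panel`
#'   (a [rating_panel()]), `excursion_errors` (data.frame: participant,
#'   movement, system, channel, trial, error — single-trial excursion
#'   errors for the repetition bootstrap), `severities`, and
#'   `detection_recovered` (count of sessions where template detection
#'   found under 2 repetitions and the marked onsets were used instead).
#' @export
simulate_study <- function(n_participants = 8, n_movements = 10, n_reps = 10,
                           severities = NULL, systems = "lowcost",
                           n_raters = 30, rater_noise = 0.35, seed = NULL,
                           ...) {
  if (is.null(severities)) {
    severities <- seq(0.1, 0.9, length.out = n_participants)
  }
  with_seed(seed, {
    score_rows <- list()
    exc_rows <- list()
    qual_items <- list()
    recovered <- 0L
    for (p in seq_len(n_participants)) {
      s_p <- severities[p]
      for (m in seq_len(n_movements)) {
        trials_by_system <- list()
        for (sys in systems) {
          cap <- if (sys == "truth") NULL else capture_model(sys)
          segs <- list()
          for (limb in c("nonparetic", "paretic")) {
            sev <- if (limb == "paretic") s_p else 0
            side <- if (limb == "paretic") "right" else "left"
            ses <- simulate_session(m, n_reps, severity = sev, cap = cap,
                                    limb_side = side, ...)
            proc <- process_session(ses, cap)
            if (proc$recovered) recovered <- recovered + 1L
            segs[[limb]] <- proc$trials
          }
          trials_by_system[[sys]] <- segs
          basis <- derive_basis(align_and_average(segs$nonparetic))
          for (limb in c("nonparetic", "paretic")) {
            sc <- score_trials(segs[[limb]], basis)
            score_rows[[length(score_rows) + 1]] <- data.frame(
              participant = p, movement = m, system = sys, limb = limb,
              trial = sc$trial, k = sc$k_used, score = sc$value
            )
            ee <- excursion_errors(segs[[limb]])
            exc_rows[[length(exc_rows) + 1]] <- data.frame(
              participant = p, movement = m, system = sys, limb = limb,
              channel = rep(angle_channels(), each = nrow(ee)),
              trial = rep(seq_len(nrow(ee)), 4),
              error = as.vector(ee)
            )
          }
        }
        qual_items[[length(qual_items) + 1]] <- data.frame(
          participant = p, movement = m, limb = "paretic",
          quality = min(max(1 - s_p + stats::rnorm(1, 0, 0.05), 0), 1)
        )
      }
    }
    items <- do.call(rbind, qual_items)
    panel <- simulate_raters(items, n_raters, rater_noise)
    structure(list(
      scores = do.call(rbind, score_rows),
      panel = panel,
      excursion_errors = do.call(rbind, exc_rows),
      severities = severities,
      detection_recovered = recovered
    ), class = "impairment_study")
  })
}

#' @export
print.impairment_study <- function(x, ...) {
  sc <- x$scores
  cat(sprintf("<impairment_study> %d participants x %d movements | systems: %s\n",
              length(unique(sc$participant)), length(unique(sc$movement)),
              paste(unique(sc$system), collapse = ", ")))
  cat(sprintf("  %d scored trials, %d-rater panel\n",
              nrow(sc), length(unique(x$panel$entries$rater))))
  invisible(x)
}

# Run one simulated session through the measurement pipeline: filter,
# joint angles, template segmentation. Falls back to cutting at the marked
# onsets when detection finds fewer than 2 repetitions.
process_session <- function(ses, cap, common_length = 100, min_corr = 0.5) {
  if (is.null(cap)) {
    series <- ses$truth
    onsets <- ses$onsets
    rep_n <- ses$rep_samples
  } else {
    rec <- lowpass_filter(ses$recording)
    series <- compute_joint_angles(rec)
    onsets <- ses$onsets_capture
    rep_n <- ses$rep_samples_capture
  }
  marked <- cbind(onsets, pmin(onsets + rep_n - 1, n_samples(series)))
  tmpl <- build_template(list(series), list(marked))
  trials <- detect_repetitions(series, tmpl, min_corr = min_corr,
                               common_length = common_length)
  recovered <- FALSE
  if (length(trials) < 2) {
    recovered <- TRUE
    segs <- lapply(seq_len(nrow(marked)), function(i) {
      resample_series(cut_series(series, marked[i, 1], marked[i, 2]),
                      common_length)
    })
    trials <- segmented_trials(segs, marked[, 1], tmpl$movement_type)
  }
  list(trials = trials, recovered = recovered)
}

#' Single-trial excursion errors of a trial set
#'
#' For each trial and joint channel, the absolute difference between the
#' trial's maximal angular excursion and the excursion of the across-trial
#' average — the error fed to the minimal-repetition bootstrap.
#'
#' @param trials a [segmented_trials()].
#' @return numeric matrix, trials x 4 channels, degrees.
#' @export
excursion_errors <- function(trials) {
  avg <- align_and_average(trials)
  ref <- apply(avg$angles, 2, function(x) diff(range(x)))
  t(vapply(trials$trials, function(s) {
    abs(apply(s$angles, 2, function(x) diff(range(x))) - ref)
  }, numeric(4)))
}
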
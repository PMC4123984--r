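# Core data containers. All are validated S3 lists; accessor helpers below.

#' Joint-angle channel names, in the fixed column order used everywhere
#'
#' Order: shoulder flexion/extension, shoulder abduction/adduction,
#' elbow flexion/extension, wrist flexion/extension. All angles in degrees.
#' @export
angle_channels <- function() {
  c("shoulder_flexext", "shoulder_abdadd", "elbow_flexext", "wrist_flexext")
}

#' Landmark labels required for joint-angle computation
#'
#' The minimal tracked set: ipsilateral shoulder (`shoulder`), contralateral
#' shoulder (`shoulder_contra`), `elbow`, `wrist`, `hand`, and a `pelvis`
#' trunk reference. Matching is case-insensitive.
#' @export
required_landmarks <- function() {
  c("shoulder", "shoulder_contra", "elbow", "wrist", "hand", "pelvis")
}

#' Construct a marker recording
#'
#' A timestamped set of 3D landmark trajectories for one limb and session.
#' Positions are in meters; time in seconds.
#'
#' @param time numeric vector of strictly increasing timestamps (s).
#' @param positions numeric matrix, one row per sample, columns
#'   `<label>_x`, `<label>_y`, `<label>_z` for every landmark, in label order.
#' @param labels character vector of landmark names.
#' @param sample_rate sampling rate in Hz; inferred from `time` when `NULL`.
#' @param limb_side `"left"` or `"right"`.
#' @param system_tag `"standard"`, `"lowcost"`, or `"truth"` for synthetic
#'   noise-free data.
#' @param session_id opaque identifier carried through the pipeline.
#' @return object of class `marker_recording`.
#' @export
marker_recording <- function(time, positions, labels, sample_rate = NULL,
                             limb_side = "left", system_tag = "standard",
                             session_id = "session") {
  positions <- unname(as.matrix(positions))
  storage.mode(positions) <- "double"
  if (is.null(sample_rate)) {
    if (length(time) < 2) stop("cannot infer sample rate from fewer than 2 samples")
    sample_rate <- 1 / stats::median(diff(time))
  }
  rec <- structure(list(
    time = as.numeric(time),
    positions = positions,
    labels = as.character(labels),
    sample_rate = as.numeric(sample_rate),
    limb_side = match.arg(limb_side, c("left", "right")),
    system_tag = match.arg(system_tag, c("standard", "lowcost", "truth")),
    session_id = as.character(session_id)
  ), class = "marker_recording")
  validate_marker_recording(rec)
}

validate_marker_recording <- function(rec) {
  with(rec, {
    if (sample_rate <= 0) stop("sample_rate must be positive")
    if (length(time) != nrow(positions)) {
      stop("time vector and position matrix disagree on sample count")
    }
    if (ncol(positions) != 3L * length(labels)) {
      stop("position matrix must have 3 columns (x, y, z) per landmark")
    }
    dt <- diff(time)
    if (length(dt) > 0) {
      if (any(dt <= 0)) stop("timestamps must be strictly increasing")
      med <- stats::median(dt)
      if (any(abs(dt - med) > 0.01 * med + 1e-12)) {
        stop("timestamps not uniformly spaced (jitter exceeds 1% of the sample interval)")
      }
    }
    missing <- setdiff(required_landmarks(), tolower(labels))
    if (length(missing) > 0) {
      stop(sprintf("required landmark(s) missing: %s (required set: %s)",
                   paste(missing, collapse = ", "),
                   paste(required_landmarks(), collapse = ", ")))
    }
    if (anyNA(positions)) {
      stop("marker gaps remain; gaps over 3 consecutive samples invalidate the trial")
    }
  })
  rec
}

#' @export
print.marker_recording <- function(x, ...) {
  cat(sprintf("<marker_recording> %s | %s limb | %s system\n",
              x$session_id, x$limb_side, x$system_tag))
  cat(sprintf("  %d samples at %.4g Hz (%.2f s), %d landmarks: %s\n",
              length(x$time), x$sample_rate,
              if (length(x$time) > 1) diff(range(x$time)) else 0,
              length(x$labels), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Extract one landmark's n x 3 coordinate matrix from a recording
#' @param rec a `marker_recording`.
#' @param label landmark name (case-insensitive).
#' @export
landmark_xyz <- function(rec, label) {
  i <- match(tolower(label), tolower(rec$labels))
  if (is.na(i)) stop(sprintf("landmark '%s' not present", label))
  rec$positions[, (3 * (i - 1) + 1):(3 * i), drop = FALSE]
}

#' Construct a joint-angle series
#'
#' Four physiological joint angles (degrees) over time for one limb. Column
#' order is fixed (see [angle_channels()]): elbow and wrist angles lie in
#' [0, 180]; shoulder angles in [-180, 180] (physiological range about
#' [-90, 180]).
#'
#' @param angles numeric matrix, time x 4, degrees.
#' @param sample_rate Hz.
#' @param limb_side,system_tag,provenance metadata carried along.
#' @return object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(angles, sample_rate, limb_side = "left",
                               system_tag = "standard", provenance = "") {
  angles <- as.matrix(angles)
  storage.mode(angles) <- "double"
  dimnames(angles) <- list(NULL, angle_channels())
  s <- structure(list(
    angles = angles,
    sample_rate = as.numeric(sample_rate),
    limb_side = limb_side,
    system_tag = system_tag,
    provenance = as.character(provenance)
  ), class = "joint_angle_series")
  validate_joint_angle_series(s)
}

validate_joint_angle_series <- function(s) {
  if (ncol(s$angles) != 4L) stop("angle matrix must have exactly 4 channels")
  if (anyNA(s$angles)) stop("joint-angle series must not contain missing values")
  if (s$sample_rate <= 0) stop("sample_rate must be positive")
  tol <- 1e-6
  ew <- s$angles[, 3:4]
  if (any(ew < -tol | ew > 180 + tol)) {
    stop("elbow/wrist angles outside [0, 180] degrees")
  }
  sh <- s$angles[, 1:2]
  if (any(sh < -180 - tol | sh > 180 + tol)) {
    stop("shoulder angles outside [-180, 180] degrees")
  }
  s
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %d samples at %.4g Hz | %s limb | %s\n",
              nrow(x$angles), x$sample_rate, x$limb_side, x$system_tag))
  rng <- apply(x$angles, 2, range)
  for (j in seq_len(4)) {
    cat(sprintf("  %-16s [%7.2f, %7.2f] deg\n",
                angle_channels()[j], rng[1, j], rng[2, j]))
  }
  invisible(x)
}

#' Number of time samples in a joint-angle series
#' @param series a `joint_angle_series`.
#' @export
n_samples <- function(series) nrow(series$angles)

#' Construct a movement template
#'
#' The per-movement mean joint-angle trace used as a matched filter for
#' repetition detection and alignment.
#'
#' @param traces numeric matrix, template_length x 4, degrees.
#' @param movement_type movement identifier (1-10 for the built-in presets).
#' @param sample_rate Hz of the template time base.
#' @export
movement_template <- function(traces, movement_type, sample_rate) {
  traces <- as.matrix(traces)
  storage.mode(traces) <- "double"
  dimnames(traces) <- list(NULL, angle_channels())
  if (anyNA(traces)) stop("template traces must not contain missing values")
  if (nrow(traces) < 10) stop("template must have at least 10 samples")
  structure(list(
    traces = traces,
    movement_type = movement_type,
    template_length = nrow(traces),
    sample_rate = as.numeric(sample_rate)
  ), class = "movement_template")
}

#' @export
print.movement_template <- function(x, ...) {
  cat(sprintf("<movement_template> movement %s | %d samples at %.4g Hz\n",
              as.character(x$movement_type), x$template_length, x$sample_rate))
  invisible(x)
}

#' Construct a set of segmented, length-normalized trials
#'
#' @param trials list of `joint_angle_series`, all of identical length.
#' @param onsets integer sample indices of detected onsets in the source
#'   series, strictly increasing.
#' @param movement_type movement identifier.
#' @export
segmented_trials <- function(trials, onsets, movement_type = NA) {
  if (length(trials) != length(onsets)) stop("one onset per trial required")
  if (length(trials) > 0) {
    lens <- vapply(trials, n_samples, integer(1))
    if (length(unique(lens)) > 1) stop("all trials must have identical length")
    if (length(onsets) > 1 && any(diff(onsets) <= 0)) {
      stop("onsets must be strictly increasing")
    }
  }
  structure(list(trials = trials, onsets = as.integer(onsets),
                 movement_type = movement_type),
            class = "segmented_trials")
}

#' @export
print.segmented_trials <- function(x, ...) {
  cat(sprintf("<segmented_trials> %d trial(s), movement %s\n",
              length(x$trials), as.character(x$movement_type)))
  if (length(x$trials) > 0) {
    cat(sprintf("  trial length %d samples; onsets: %s\n",
                n_samples(x$trials[[1]]),
                paste(x$onsets, collapse = ", ")))
  }
  invisible(x)
}

#' @export
length.segmented_trials <- function(x) length(x$trials)

#' Construct a rating panel
#'
#' Ordinal clinical scores (0..scale_max) per participant x movement x limb
#' x rater, on the 3-point scale used for item-level motor assessment
#' (0 = no movement, 1 = slow/abnormal, 2 = normal) unless `scale_max` says
#' otherwise.
#'
#' @param entries data.frame with columns `participant`, `movement`, `limb`,
#'   `rater`, `score`.
#' @param scale_max maximal score on the ordinal scale (default 2).
#' @export
rating_panel <- function(entries, scale_max = 2) {
  needed <- c("participant", "movement", "limb", "rater", "score")
  if (!all(needed %in% names(entries))) {
    stop(sprintf("rating panel needs columns: %s", paste(needed, collapse = ", ")))
  }
  entries <- as.data.frame(entries)[needed]
  p <- structure(list(entries = entries, scale_max = as.integer(scale_max)),
                 class = "rating_panel")
  validate_rating_panel(p)
}

validate_rating_panel <- function(p) {
  sc <- p$entries$score
  bad <- which(is.na(sc) | sc != round(sc) | sc < 0 | sc > p$scale_max)
  if (length(bad) > 0) {
    stop(sprintf("score outside {0..%d} at entry row(s): %s",
                 p$scale_max, paste(utils::head(bad, 5), collapse = ", ")))
  }
  key <- do.call(paste, c(p$entries[c("participant", "movement", "limb", "rater")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (participant, movement, limb, rater) key at entry row(s): %s",
                 paste(utils::head(which(duplicated(key)), 5), collapse = ", ")))
  }
  p
}

#' @export
print.rating_panel <- function(x, ...) {
  e <- x$entries
  cat(sprintf("<rating_panel> %d entries | %d participant(s), %d movement(s), %d rater(s), scale 0..%d\n",
              nrow(e), length(unique(e$participant)),
              length(unique(e$movement)), length(unique(e$rater)), x$scale_max))
  invisible(x)
}
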
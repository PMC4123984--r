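# Landmarks -> filtered four-angle joint kinematics.
#
# Angle conventions (trunk frame, built per sample):
#   mediolateral axis m = contralateral -> ipsilateral shoulder line
#   vertical axis     v = pelvis -> mid-shoulder line, orthogonalized vs m
#   anteroposterior   a = v x m (points forward)
# Shoulder flexion/extension = angle of the upper-arm vector (shoulder->elbow)
# projected on the sagittal (a, v) plane, measured from straight-down
# (flexion positive forward). Shoulder abduction/adduction = same vector on
# the frontal (m, v) plane from straight-down (abduction positive lateral).
# Elbow = 3D angle between (elbow->shoulder) and (elbow->wrist); wrist = 3D
# angle between (wrist->elbow) and (wrist->hand). Defining the frame entirely
# from tracked landmarks makes the angles invariant to rigid motion of the
# whole landmark set.

row_norm <- function(m) sqrt(rowSums(m^2))

row_unit <- function(m) {
  n <- row_norm(m)
  m / ifelse(n > 0, n, 1)
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_dot <- function(a, b) rowSums(a * b)

# 3D angle at vertex between row-wise vectors u and w, in degrees; returns NA
# where either vector is (near) zero length.
row_angle_deg <- function(u, w, tol = 1e-9) {
  nu <- row_norm(u); nw <- row_norm(w)
  c_ <- row_dot(u, w) / pmax(nu * nw, tol)
  out <- acos(pmin(pmax(c_, -1), 1)) * 180 / pi
  out[nu < tol | nw < tol] <- NA_real_
  out
}

# Zero-phase filtering with odd-reflection end padding, so edge transients
# from the filter's zero initial conditions decay inside the discarded pad
# rather than inside the data (DC gain is exactly 1 on constant input).
zero_phase_filter <- function(x, bf, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  if (pad < 1) return(signal::filtfilt(bf, x))
  front <- 2 * x[1] - x[seq(pad + 1, 2)]
  back <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- signal::filtfilt(bf, c(front, x, back))
  y[(pad + 1):(pad + n)]
}

#' Low-pass filter a marker recording
#'
#' Zero-phase (forward-backward) Butterworth low-pass applied to each
#' coordinate channel independently, so the effective magnitude response is
#' the squared single-pass response and no phase lag is introduced —
#' temporal alignment downstream is unaffected.
#'
#' @param rec a [marker_recording()].
#' @param cutoff_hz cutoff frequency (default 6 Hz).
#' @param order filter order of a single pass (default 2).
#' @return filtered [marker_recording()] of identical length.
#' @export
lowpass_filter <- function(rec, cutoff_hz = 6, order = 2) {
  nyq <- rec$sample_rate / 2
  if (cutoff_hz >= nyq) {
    stop(sprintf("cutoff %.4g Hz must be below the Nyquist frequency %.4g Hz",
                 cutoff_hz, nyq))
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  pad <- ceiling(6 * rec$sample_rate / cutoff_hz)
  rec$positions <- apply(rec$positions, 2, function(x) {
    zero_phase_filter(x, bf, pad)
  })
  rec
}

#' Compute the four joint angles from a marker recording
#'
#' Samples where a landmark triplet is degenerate (collinear or coincident,
#' leaving an angle undefined) are flagged and carry the last valid value;
#' if more than `max_degenerate_fraction` of samples are degenerate the
#' trial is invalid and an error is raised.
#'
#' @param rec a [marker_recording()] (low-pass filtered input recommended).
#' @param max_degenerate_fraction trial-invalidation threshold (default 0.10).
#' @return a [joint_angle_series()] at the recording's sample rate, with an
#'   attribute `degenerate` holding the flagged sample indices.
#' @export
compute_joint_angles <- function(rec, max_degenerate_fraction = 0.10) {
  S <- landmark_xyz(rec, "shoulder")
  C <- landmark_xyz(rec, "shoulder_contra")
  E <- landmark_xyz(rec, "elbow")
  W <- landmark_xyz(rec, "wrist")
  H <- landmark_xyz(rec, "hand")
  P <- landmark_xyz(rec, "pelvis")

  tol <- 1e-9
  m_raw <- S - C
  m_n <- row_norm(m_raw)
  m <- m_raw / pmax(m_n, tol)
  mid <- (S + C) / 2
  v_raw <- mid - P
  v_raw <- v_raw - m * row_dot(v_raw, m)   # orthogonalize against shoulder line
  v_n <- row_norm(v_raw)
  v <- v_raw / pmax(v_n, tol)
  a <- row_cross(v, m)

  u <- E - S                                # upper-arm vector
  um <- row_dot(u, m); ua <- row_dot(u, a); uv <- row_dot(u, v)
  sf <- atan2(ua, -uv) * 180 / pi
  sa <- atan2(um, -uv) * 180 / pi
  frame_bad <- m_n < tol | v_n < tol
  shoulder_bad <- frame_bad | (abs(ua) < tol & abs(uv) < tol) |
    (abs(um) < tol & abs(uv) < tol)
  sf[shoulder_bad] <- NA_real_
  sa[shoulder_bad] <- NA_real_

  ef <- row_angle_deg(S - E, W - E)
  wf <- row_angle_deg(E - W, H - W)

  ang <- cbind(sf, sa, ef, wf)
  degen <- which(rowSums(is.na(ang)) > 0)
  if (length(degen) > nrow(ang) * max_degenerate_fraction) {
    stop(sprintf("trial invalid: %d of %d samples (%.1f%%) have degenerate poses",
                 length(degen), nrow(ang), 100 * length(degen) / nrow(ang)))
  }
  if (length(degen) > 0) {
    for (j in seq_len(4)) {
      x <- ang[, j]
      if (anyNA(x)) {
        ok <- which(!is.na(x))
        if (length(ok) == 0) stop("trial invalid: a joint angle is undefined at every sample")
        # carry last valid value; leading NAs take the first valid one
        idx <- findInterval(seq_along(x), ok)
        idx[idx == 0] <- 1
        ang[, j] <- x[ok[idx]]
      }
    }
  }
  out <- joint_angle_series(ang, sample_rate = rec$sample_rate,
                            limb_side = rec$limb_side,
                            system_tag = rec$system_tag,
                            provenance = rec$session_id)
  attr(out, "degenerate") <- degen
  out
}

#' Resample a joint-angle series to a fixed number of points
#'
#' Linear interpolation of each channel onto `n_points` equally spaced
#' points spanning the original time range. All cross-trial arithmetic in
#' the pipeline is done on the common 100-point base.
#'
#' @param series a [joint_angle_series()] with at least 2 samples.
#' @param n_points number of output samples (>= 2; default 100).
#' @return resampled [joint_angle_series()].
#' @export
resample_series <- function(series, n_points = 100) {
  if (n_points < 2) stop("n_points must be at least 2")
  n <- n_samples(series)
  if (n < 2) stop("series must have at least 2 samples")
  t_old <- (seq_len(n) - 1) / series$sample_rate
  t_new <- seq(0, t_old[n], length.out = n_points)
  ang <- apply(series$angles, 2, function(x) {
    stats::approx(t_old, x, xout = t_new)$y
  })
  joint_angle_series(ang, sample_rate = (n_points - 1) / t_old[n],
                     limb_side = series$limb_side,
                     system_tag = series$system_tag,
                     provenance = series$provenance)
}

# Cut a sample-index window [from, to] out of a series.
cut_series <- function(series, from, to) {
  joint_angle_series(series$angles[from:to, , drop = FALSE],
                     sample_rate = series$sample_rate,
                     limb_side = series$limb_side,
                     system_tag = series$system_tag,
                     provenance = series$provenance)
}
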
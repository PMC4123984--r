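# Template-based repetition detection and temporal alignment.
#
# Three-step procedure: (1) movement starts/ends marked in a subset of data
# (or seeded automatically when one movement type per recording),
# (2) marked segments averaged per joint channel into a mean trace that acts
# as a matched template, (3) repetitions located at the local maxima of the
# sliding correlation-coefficient profile between the series and the
# template, then cut and length-normalized.

# Sliding dot product: out[t] = sum(x[t:(t+L-1)] * w), t = 1..N-L+1.
sliding_dot <- function(x, w) {
  stats::convolve(x, w, conj = TRUE, type = "filter")
}

# Sliding Pearson correlation of every length-L window of x with w.
# Windows (or a template channel) with zero variance correlate as 0.
sliding_corr <- function(x, w) {
  L <- length(w)
  N <- length(x)
  if (N < L) stop("series shorter than template")
  ones <- rep(1, L)
  s1 <- sliding_dot(x, ones)          # window sums
  s2 <- sliding_dot(x^2, ones)
  cross <- sliding_dot(x, w)
  mw <- mean(w)
  vw <- sum((w - mw)^2)
  vx <- pmax(s2 - s1^2 / L, 0)
  cov_ <- cross - s1 * mw
  denom <- sqrt(vx * vw)
  r <- ifelse(denom > 1e-12, cov_ / denom, 0)
  pmin(pmax(r, -1), 1)
}

#' Build a movement template from marked segments
#'
#' Cuts the marked (start, end) windows out of their series, resamples each
#' to a common length, and averages per joint channel. With a single marked
#' segment the template is that segment resampled.
#'
#' @param series_list list of [joint_angle_series()], all at one sample rate.
#' @param onsets_list list (parallel to `series_list`) of two-column
#'   matrices/data.frames of (start, end) sample indices, one row per
#'   marked segment.
#' @param movement_type identifier stored on the template.
#' @param template_length output length in samples; default the rounded
#'   median marked-segment length.
#' @return a [movement_template()].
#' @export
build_template <- function(series_list, onsets_list, movement_type = NA,
                           template_length = NULL) {
  if (length(series_list) != length(onsets_list)) {
    stop("series_list and onsets_list must have the same length")
  }
  rates <- vapply(series_list, function(s) s$sample_rate, numeric(1))
  if (length(unique(round(rates, 6))) > 1) {
    stop("all series must share one sample rate")
  }
  segs <- list()
  for (i in seq_along(series_list)) {
    on <- as.matrix(onsets_list[[i]])
    for (r in seq_len(nrow(on))) {
      segs[[length(segs) + 1]] <- cut_series(series_list[[i]], on[r, 1], on[r, 2])
    }
  }
  if (length(segs) == 0) stop("at least one marked segment is required")
  lens <- vapply(segs, n_samples, integer(1))
  if (max(lens) / min(lens) > 3) {
    warning(sprintf("marked segments differ grossly in duration (%d to %d samples)",
                    min(lens), max(lens)))
  }
  if (is.null(template_length)) template_length <- max(10L, round(stats::median(lens)))
  traces <- Reduce(`+`, lapply(segs, function(s) {
    resample_series(s, template_length)$angles
  })) / length(segs)
  movement_template(traces, movement_type = movement_type, sample_rate = rates[1])
}

#' Seed a template automatically from the first high-energy segment
#'
#' For recordings holding a single movement type, manual marking can be
#' omitted: the first contiguous run where the smoothed joint-space
#' deviation from rest exceeds `energy_frac` of its maximum is taken as the
#' seed segment, and the template is that segment.
#'
#' @param series a [joint_angle_series()].
#' @param energy_frac activity threshold as a fraction of peak deviation
#'   (default 0.2).
#' @param movement_type identifier stored on the template.
#' @return a [movement_template()].
#' @export
auto_template <- function(series, energy_frac = 0.2, movement_type = NA) {
  X <- series$angles
  dev <- rowSums(sweep(X, 2, X[1, ])^2)
  k <- max(3L, round(series$sample_rate * 0.1))
  dev <- stats::filter(dev, rep(1 / k, k), sides = 2)
  dev[is.na(dev)] <- 0
  act <- dev > energy_frac * max(dev)
  r <- rle(as.vector(act))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)[1]
  if (is.na(i)) stop("no high-energy segment found to seed a template")
  from <- max(1L, starts[i] - k)
  to <- min(nrow(X), ends[i] + k)
  if (to - from + 1 < 10) stop("seed segment shorter than 10 samples")
  movement_template(series$angles[from:to, , drop = FALSE],
                    movement_type = movement_type,
                    sample_rate = series$sample_rate)
}

#' Detect movement repetitions by sliding template correlation
#'
#' The Pearson correlation between the template and every same-length
#' window of the series is computed per joint channel and averaged
#' (unweighted) across the four channels. Local maxima of this profile
#' above `min_corr`, separated by at least `min_separation` of the template
#' length, become repetition onsets; each repetition is cut and resampled
#' to `common_length` points.
#'
#' @param series a [joint_angle_series()] at the template's sample rate.
#' @param template a [movement_template()].
#' @param min_corr detection threshold on the averaged correlation
#'   (default 0.7).
#' @param min_separation minimal onset spacing as a fraction of template
#'   length (default 0.5).
#' @param common_length length-normalized trial length (default 100).
#' @return a [segmented_trials()]; when no peak clears the threshold the
#'   result is empty and carries attributes `max_corr` (the best correlation
#'   found) and `profile`.
#' @export
detect_repetitions <- function(series, template, min_corr = 0.7,
                               min_separation = 0.5, common_length = 100) {
  L <- template$template_length
  N <- n_samples(series)
  if (N < L) stop("series is shorter than the template")
  # channels where the template is constant carry no correlation
  # information (correlation undefined) and are excluded from the mean
  informative <- which(apply(template$traces, 2, stats::sd) > 1e-9)
  if (length(informative) == 0) stop("template is constant on every channel")
  prof <- rowMeans(matrix(vapply(informative, function(j) {
    sliding_corr(series$angles[, j], template$traces[, j])
  }, numeric(N - L + 1)), ncol = length(informative)))

  # local maxima above threshold (plateau-tolerant on the left)
  n <- length(prof)
  cand <- which(prof >= min_corr)
  is_peak <- function(t) {
    (t == 1 || prof[t] >= prof[t - 1]) && (t == n || prof[t] > prof[t + 1])
  }
  cand <- cand[vapply(cand, is_peak, logical(1))]
  # greedy non-maximum suppression by descending correlation
  min_sep <- ceiling(min_separation * L)
  keep <- integer(0)
  for (t in cand[order(prof[cand], decreasing = TRUE)]) {
    if (all(abs(t - keep) >= min_sep)) keep <- c(keep, t)
  }
  keep <- sort(keep)
  keep <- keep[keep + L - 1 <= N]
  if (length(keep) == 0) {
    message(sprintf("no repetition found: max sliding correlation %.3f below threshold %.2f",
                    max(prof), min_corr))
    out <- segmented_trials(list(), integer(0), template$movement_type)
    attr(out, "max_corr") <- max(prof)
    attr(out, "profile") <- prof
    return(out)
  }
  trials <- lapply(keep, function(t) {
    resample_series(cut_series(series, t, t + L - 1), common_length)
  })
  out <- segmented_trials(trials, keep, template$movement_type)
  attr(out, "profile") <- prof
  out
}

#' Average aligned trials pointwise
#'
#' Pointwise mean across trials per joint channel; the input trials are
#' already length-normalized, so the result is a mean movement trace on the
#' common time base.
#'
#' @param trials a [segmented_trials()] with at least one trial.
#' @return a [joint_angle_series()].
#' @export
align_and_average <- function(trials) {
  if (length(trials) < 1) stop("at least one trial is required")
  mean_ang <- Reduce(`+`, lapply(trials$trials, function(s) s$angles)) /
    length(trials)
  t1 <- trials$trials[[1]]
  joint_angle_series(mean_ang, sample_rate = t1$sample_rate,
                     limb_side = t1$limb_side, system_tag = t1$system_tag,
                     provenance = sprintf("mean of %d trials", length(trials)))
}
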
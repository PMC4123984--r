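# The quantitative impairment score.
#
# Principal components are derived from the averaged non-paretic joint-angle
# profiles of one movement: the four channels are demeaned and the 4x4
# covariance over time samples is eigendecomposed. Individual trials (paretic
# or non-paretic) are demeaned with their own channel means, projected onto
# the components retained to explain >= the variance threshold (default 95%),
# and back-projected; the coefficient of determination (R^2) of the
# reconstruction, pooled over channels and time, is the score. Demeaning
# makes the score immune to constant per-channel capture biases; the
# dimensionality reduction is what gives the score its sensitivity to
# abnormal inter-joint coordination.

#' Derive a principal-component basis from a mean movement trace
#'
#' @param mean_series a [joint_angle_series()] holding the across-repetition
#'   average of one movement of the (non-paretic) reference limb.
#' @param variance_threshold retain the smallest number of components whose
#'   cumulative explained-variance fraction reaches this value (default 0.95).
#' @return object of class `pc_basis` with unit-norm loadings (4 x k),
#'   the full nonincreasing eigenvalue spectrum, the channel means removed
#'   before decomposition, `k`, and the explained-variance fractions.
#' @export
derive_basis <- function(mean_series, variance_threshold = 0.95) {
  X <- mean_series$angles
  if (nrow(X) < 2) stop("at least 2 time samples are required")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- stats::cov(Xc)
  ee <- eigen(C, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  total <- sum(vals)
  if (total <= 0) stop("degenerate input: all four channels are constant")
  vecs <- ee$vectors
  # deterministic sign: largest-magnitude element of each loading positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  frac <- vals / total
  # threshold 1 means the complete basis, even for rank-deficient input
  k <- if (variance_threshold >= 1) length(vals)
       else which(cumsum(frac) >= variance_threshold - 1e-12)[1]
  structure(list(
    loadings = vecs,
    eigenvalues = vals,
    channel_means = mu,
    k = as.integer(k),
    variance_threshold = variance_threshold,
    var_fractions = frac
  ), class = "pc_basis")
}

#' @export
print.pc_basis <- function(x, ...) {
  cat(sprintf("<pc_basis> k = %d of 4 components (threshold %.2f)\n",
              x$k, x$variance_threshold))
  cat(sprintf("  explained variance: %s\n",
              paste(sprintf("%.1f%%", 100 * x$var_fractions), collapse = ", ")))
  invisible(x)
}

#' Reconstruct a trial from the retained principal components
#'
#' The trial is demeaned with its *own* per-channel means (not the basis
#' means), projected onto the `k` retained loadings, back-projected, and the
#' trial means restored. Centering each trial on itself is what removes
#' constant capture biases from the score.
#'
#' @param trial a [joint_angle_series()] on the common time base.
#' @param basis a `pc_basis` from [derive_basis()].
#' @return reconstructed [joint_angle_series()] (validation relaxed: a
#'   reconstruction may leave the physiological angle ranges).
#' @export
reconstruct <- function(trial, basis) {
  mu <- colMeans(trial$angles)
  Xc <- sweep(trial$angles, 2, mu)
  V <- basis$loadings[, seq_len(basis$k), drop = FALSE]
  Xhat <- Xc %*% V %*% t(V)
  out <- trial
  out$angles <- sweep(Xhat, 2, mu, `+`)
  out
}

#' Score one trial against a principal-component basis
#'
#' The quantitative impairment score: `1 - SS_residual / SS_total`, pooled
#' over the four channels and all time points, with `SS_total` taken about
#' the trial's per-channel means. 1 means the trial lies in the span of the
#' retained components; lower values mean the reference components represent
#' the movement poorly. Scores can be negative and are never clipped.
#'
#' @param trial a [joint_angle_series()] on the common time base.
#' @param basis a `pc_basis`.
#' @param pooling `"pooled"` (default; one R^2 over channels and time) or
#'   `"per_channel"` (mean of per-channel R^2 values).
#' @return one-row data.frame with columns `value`, `k_used`, `valid`;
#'   a trial with zero total variance yields `valid = FALSE` and `value = NA`.
#' @export
score_trial <- function(trial, basis, pooling = c("pooled", "per_channel")) {
  pooling <- match.arg(pooling)
  mu <- colMeans(trial$angles)
  Xc <- sweep(trial$angles, 2, mu)
  V <- basis$loadings[, seq_len(basis$k), drop = FALSE]
  R <- Xc - Xc %*% V %*% t(V)
  if (pooling == "pooled") {
    ss_tot <- sum(Xc^2)
    if (ss_tot <= 0) {
      return(data.frame(value = NA_real_, k_used = basis$k, valid = FALSE))
    }
    val <- 1 - sum(R^2) / ss_tot
  } else {
    ss_tot <- colSums(Xc^2)
    if (all(ss_tot <= 0)) {
      return(data.frame(value = NA_real_, k_used = basis$k, valid = FALSE))
    }
    ok <- ss_tot > 0
    val <- mean(1 - colSums(R^2)[ok] / ss_tot[ok])
  }
  data.frame(value = val, k_used = basis$k, valid = TRUE)
}

#' Baseline scores of the reference limb's own trials
#'
#' Scores each non-paretic trial against the basis built from the averaged
#' non-paretic movement, giving the inherent score variability of an
#' unimpaired limb — the reference distribution against which paretic
#' scores are read. By default the basis passed in is used as-is
#' (`"include_all"`); with `mode = "leave_one_out"` each trial is scored
#' against a basis rebuilt from the average of the *other* trials.
#'
#' @param nonparetic_trials a [segmented_trials()] of the reference limb.
#' @param basis the `pc_basis` built from these trials' average.
#' @param mode `"include_all"` (default) or `"leave_one_out"`.
#' @param pooling passed to [score_trial()].
#' @return data.frame with one row per trial: `trial`, `value`, `k_used`,
#'   `valid`.
#' @export
score_baseline <- function(nonparetic_trials, basis,
                           mode = c("include_all", "leave_one_out"),
                           pooling = "pooled") {
  mode <- match.arg(mode)
  n <- length(nonparetic_trials)
  if (n < 1) stop("at least one trial is required")
  rows <- lapply(seq_len(n), function(i) {
    b <- basis
    if (mode == "leave_one_out" && n > 1) {
      rest <- segmented_trials(nonparetic_trials$trials[-i],
                               nonparetic_trials$onsets[-i],
                               nonparetic_trials$movement_type)
      b <- derive_basis(align_and_average(rest), basis$variance_threshold)
    }
    cbind(trial = i, score_trial(nonparetic_trials$trials[[i]], b, pooling))
  })
  do.call(rbind, rows)
}

#' Score every trial of a segmented set
#'
#' @param trials a [segmented_trials()].
#' @param basis a `pc_basis`.
#' @param pooling passed to [score_trial()].
#' @return data.frame with one row per trial: `trial`, `value`, `k_used`,
#'   `valid`.
#' @export
score_trials <- function(trials, basis, pooling = "pooled") {
  do.call(rbind, lapply(seq_along(trials$trials), function(i) {
    cbind(trial = i, score_trial(trials$trials[[i]], basis, pooling))
  }))
}
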
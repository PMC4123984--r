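# Inter-system accuracy: RMS and maximal-excursion errors of a low-cost
# capture system relative to the standard system, per joint channel.
# RMS error is sensitive to constant biases; excursion error is not — the
# pair jointly separates bias from noise.

#' Per-channel RMS error between two aligned joint-angle series
#'
#' @param a,b [joint_angle_series()] of identical length (resample to the
#'   common base and align on movement onset first).
#' @return named numeric vector of 4 RMS errors in degrees.
#' @export
rms_error <- function(a, b) {
  if (n_samples(a) != n_samples(b)) {
    stop(sprintf("length mismatch: %d vs %d samples (resample to a common base first)",
                 n_samples(a), n_samples(b)))
  }
  sqrt(colMeans((a$angles - b$angles)^2))
}

#' Per-channel absolute maximal-excursion error
#'
#' Absolute difference of the joint excursions (max - min over the
#' movement) captured by the two systems. Invariant to constant offsets.
#'
#' @param a,b [joint_angle_series()] of identical length.
#' @return named numeric vector of 4 errors in degrees.
#' @export
excursion_error <- function(a, b) {
  if (n_samples(a) != n_samples(b)) {
    stop(sprintf("length mismatch: %d vs %d samples (resample to a common base first)",
                 n_samples(a), n_samples(b)))
  }
  exc <- function(X) apply(X, 2, function(x) diff(range(x)))
  abs(exc(a$angles) - exc(b$angles))
}

#' Angular-error report of a low-cost system against the standard system
#'
#' Takes paired single trials from the two systems (same movements, same
#' repetitions, onset-aligned on the common time base) and tabulates, per
#' joint channel: mean RMS error in degrees and as % of the maximal range
#' of motion, and mean absolute maximal-excursion error in degrees and as
#' % of max. The "% of max" denominator is the per-channel maximal range of
#' motion observed across the *standard*-system trials of that movement
#' (the standard system is the gold standard). Rows are aggregated per
#' movement x limb, plus grand mean +/- s.d. rows across movements and limbs.
#'
#' @param standard,lowcost parallel lists of [joint_angle_series()] trials.
#' @param movement,limb vectors (parallel to the trial lists) labelling each
#'   trial; defaults to one group.
#' @return list with `per_movement` (data.frame: movement, limb, channel,
#'   rms_deg, rms_pct, excursion_deg, excursion_pct) and `grand`
#'   (data.frame: channel, metric, mean, sd).
#' @export
system_error_report <- function(standard, lowcost,
                                movement = rep(1L, length(standard)),
                                limb = rep("left", length(standard))) {
  if (length(standard) != length(lowcost)) {
    stop("standard and lowcost trial lists must be parallel")
  }
  if (length(standard) == 0) stop("no trials supplied")
  ch <- angle_channels()
  rms <- t(mapply(rms_error, standard, lowcost))
  exc <- t(mapply(excursion_error, standard, lowcost))
  key <- interaction(movement, limb, drop = TRUE)

  # per-movement maximal range of motion from the standard system
  rows <- list()
  for (g in levels(key)) {
    i <- which(key == g)
    ranges <- sapply(standard[i], function(s) {
      apply(s$angles, 2, function(x) diff(range(x)))
    })                                      # 4 x n_trials
    max_rom <- apply(ranges, 1, max)
    m_rms <- colMeans(rms[i, , drop = FALSE])
    m_exc <- colMeans(exc[i, , drop = FALSE])
    rows[[g]] <- data.frame(
      movement = movement[i[1]], limb = limb[i[1]], channel = ch,
      rms_deg = unname(m_rms),
      rms_pct = unname(100 * m_rms / max_rom),
      excursion_deg = unname(m_exc),
      excursion_pct = unname(100 * m_exc / max_rom),
      row.names = NULL
    )
  }
  per_movement <- do.call(rbind, c(rows, make.row.names = FALSE))
  grand <- do.call(rbind, lapply(ch, function(cc) {
    sub <- per_movement[per_movement$channel == cc, ]
    do.call(rbind, lapply(c("rms_deg", "rms_pct", "excursion_deg", "excursion_pct"),
                          function(m) {
      data.frame(channel = cc, metric = m,
                 mean = mean(sub[[m]]), sd = stats::sd(sub[[m]]))
    }))
  }))
  list(per_movement = per_movement, grand = grand)
}
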
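# Reliability statistics: minimal-repetition bootstrap, raters-to-match
# bootstrap, per-rater ICC, quantitative-vs-qualitative regression with
# analytic power, and leave-one-subject-out decoding.

# Evaluate code under a fixed seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Bootstrap mean-squared error of a k-sample mean around the overall mean,
# for k = 1..K: mean over n_draws of (mean(draw of size k) - mean(values))^2.
bootstrap_mse_curve <- function(values, k_grid, n_draws) {
  mu <- mean(values)
  vapply(k_grid, function(k) {
    draws <- matrix(sample(values, k * n_draws, replace = TRUE), nrow = k)
    mean((colMeans(draws) - mu)^2)
  }, numeric(1))
}

new_bootstrap_result <- function(k_grid, error_curve, threshold, k_star,
                                 n_draws, seed, criterion = NA_character_) {
  structure(list(k_grid = k_grid, error_curve = error_curve,
                 threshold = threshold, k_star = k_star,
                 n_draws = n_draws, seed = seed, criterion = criterion),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> n_draws = %d, seed = %s, threshold = %.4g\n",
              x$n_draws, as.character(x$seed), x$threshold))
  ks <- if (is.na(x$k_star)) "not reached" else as.character(x$k_star)
  cat(sprintf("  k* = %s over grid 1..%d\n", ks, max(x$k_grid)))
  invisible(x)
}

#' Minimal number of movement repetitions by bootstrap
#'
#' `trial_errors` are the per-trial errors of one movement and participant:
#' absolute differences between the maximal angular excursion of a single
#' trial and the maximal excursion of the across-trial average. For each
#' k, k errors are drawn with replacement `n_draws` times and the bootstrap
#' error at k is the mean squared deviation of the k-draw mean from the
#' overall mean error. `k_star` is the first k whose bootstrap error falls
#' below the criterion derived from the (1 - alpha) confidence interval of
#' the mean error: with `criterion = "half-width"` (default) the squared CI
#' half-width (t * SE)^2, with `"lower-bound"` the CI lower bound itself
#' (the literal reading of the crossing rule).
#'
#' @param trial_errors numeric vector of per-trial errors (>= 2 trials).
#' @param alpha CI level complement (default 0.05).
#' @param n_draws bootstrap resamples per k (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param criterion `"half-width"` or `"lower-bound"`.
#' @param k_max largest repetition count examined; default the number of
#'   trials available.
#' @return a `bootstrap_result`.
#' @export
min_repetitions <- function(trial_errors, alpha = 0.05, n_draws = 1000,
                            seed = NULL,
                            criterion = c("half-width", "lower-bound"),
                            k_max = length(trial_errors)) {
  criterion <- match.arg(criterion)
  n <- length(trial_errors)
  if (n < 2) stop("at least 2 trials are required")
  k_grid <- seq_len(k_max)
  curve <- with_seed(seed, bootstrap_mse_curve(trial_errors, k_grid, n_draws))
  se <- stats::sd(trial_errors) / sqrt(n)
  tq <- stats::qt(1 - alpha / 2, df = n - 1)
  threshold <- if (criterion == "half-width") (tq * se)^2
               else mean(trial_errors) - tq * se
  hit <- which(curve <= threshold)
  k_star <- if (length(hit) > 0) k_grid[hit[1]] else NA_integer_
  new_bootstrap_result(k_grid, curve, threshold, k_star, n_draws, seed, criterion)
}

panel_key <- function(df) {
  cols <- intersect(c("participant", "movement", "limb"), names(df))
  interaction(df[cols], drop = TRUE, sep = "|")
}

#' Number of human raters that match automated-scoring performance
#'
#' For each (participant, movement) key, m raters' scores are drawn with
#' replacement `n_draws` times; the rater error at m is the mean squared
#' deviation of the m-rater mean score from the full-panel mean score. The
#' key's `k_star` is the smallest m whose rater error falls below that
#' key's model error (the squared error of the automated score on the
#' qualitative scale); keys whose rater error never falls below the model
#' error by the maximal rater count are flagged "not reached" (NA).
#'
#' @param panel a [rating_panel()] with >= 2 raters.
#' @param model_errors data.frame with the panel's key columns plus `error`
#'   (the automated model's squared error per key).
#' @param n_draws bootstrap resamples per m (default 1000).
#' @param seed RNG seed.
#' @param m_max largest rater count examined; default the panel's rater count.
#' @return list of class `raters_match`: `per_key` (data.frame with key
#'   columns, `k_star`, `model_error`), `summary` (mean, sd, n_reached,
#'   n_keys), and one `bootstrap_result` per key in `curves`.
#' @export
raters_to_match <- function(panel, model_errors, n_draws = 1000, seed = NULL,
                            m_max = NULL) {
  e <- panel$entries
  if (length(unique(e$rater)) < 2) stop("at least 2 raters are required")
  key_cols <- intersect(c("participant", "movement", "limb"),
                        names(model_errors))
  if (length(key_cols) == 0 || !"error" %in% names(model_errors)) {
    stop("model_errors needs key columns (participant/movement[/limb]) and 'error'")
  }
  e$key <- do.call(paste, c(e[key_cols], sep = "|"))
  me <- model_errors
  me$key <- do.call(paste, c(me[key_cols], sep = "|"))
  missing <- setdiff(unique(e$key), me$key)
  if (length(missing) > 0) {
    stop(sprintf("model_errors missing key(s): %s",
                 paste(utils::head(missing, 5), collapse = "; ")))
  }
  keys <- unique(e$key)
  if (is.null(m_max)) m_max <- length(unique(e$rater))
  m_grid <- seq_len(m_max)
  res <- with_seed(seed, {
    lapply(keys, function(kk) {
      sc <- e$score[e$key == kk]
      merr <- me$error[match(kk, me$key)]
      curve <- bootstrap_mse_curve(sc, m_grid, n_draws)
      hit <- which(curve < merr)
      k_star <- if (length(hit) > 0) m_grid[hit[1]] else NA_integer_
      new_bootstrap_result(m_grid, curve, merr, k_star, n_draws, seed)
    })
  })
  k_stars <- vapply(res, function(r) as.numeric(r$k_star), numeric(1))
  per_key <- cbind(me[match(keys, me$key), key_cols, drop = FALSE],
                   data.frame(k_star = k_stars,
                              model_error = me$error[match(keys, me$key)]))
  rownames(per_key) <- NULL
  reached <- k_stars[!is.na(k_stars)]
  structure(list(
    per_key = per_key,
    summary = data.frame(mean = mean(reached), sd = stats::sd(reached),
                         n_reached = length(reached), n_keys = length(keys)),
    curves = stats::setNames(res, keys)
  ), class = "raters_match")
}

#' @export
print.raters_match <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<raters_match> k* = %.2f +/- %.2f raters (%d of %d keys reached)\n",
              s$mean, s$sd, s$n_reached, s$n_keys))
  invisible(x)
}

# ICC(2,1): two-way random effects, absolute agreement, single measurement,
# from the two-way ANOVA mean squares of an n (items) x k (raters) matrix.
icc21 <- function(M) {
  n <- nrow(M); k <- ncol(M)
  row_m <- rowMeans(M); col_m <- colMeans(M); g <- mean(M)
  MSR <- k * sum((row_m - g)^2) / (n - 1)
  MSC <- n * sum((col_m - g)^2) / (k - 1)
  SSE <- sum((M - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + g)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (denom <= 0) return(NA_real_)
  (MSR - MSE) / denom
}

#' Per-rater intraclass correlation against the group mean
#'
#' For each rater, the ICC between that rater's scores and the across-rater
#' mean score over all (participant x movement x limb) items, as a measure
#' of inter-rater reliability. Form: ICC(2,1) — two-way random effects,
#' absolute agreement, single measurement.
#'
#' @param panel a [rating_panel()] with >= 2 raters and >= 2 items.
#' @return data.frame with columns `rater`, `icc`; zero between-item
#'   variance yields `NA` with a warning.
#' @export
icc_per_rater <- function(panel) {
  e <- panel$entries
  raters <- sort(unique(e$rater))
  if (length(raters) < 2) stop("at least 2 raters are required")
  e$item <- do.call(paste, c(e[c("participant", "movement", "limb")], sep = "|"))
  items <- unique(e$item)
  if (length(items) < 2) stop("at least 2 items are required")
  M <- matrix(NA_real_, length(items), length(raters),
              dimnames = list(items, raters))
  M[cbind(match(e$item, items), match(e$rater, raters))] <- e$score
  if (anyNA(M)) stop("panel is not complete: every rater must score every item")
  group_mean <- rowMeans(M)
  if (stats::var(group_mean) == 0) {
    warning("zero between-item variance: ICC undefined")
    return(data.frame(rater = raters, icc = NA_real_))
  }
  icc <- vapply(seq_along(raters), function(j) icc21(cbind(M[, j], group_mean)),
                numeric(1))
  data.frame(rater = raters, icc = icc)
}

#' Regression of qualitative on quantitative scores, with analytic power
#'
#' Ordinary least squares of the qualitative (clinical) score on the
#' quantitative (motion-capture) score over matched items, with the Pearson
#' correlation, its two-sided p value, and the power of the correlation at
#' `alpha` computed from the Fisher z approximation.
#'
#' @param quant,qual numeric vectors of matched scores (>= 3 points).
#' @param alpha significance level for the power computation (default 0.05).
#' @return list: `slope`, `offset`, `r`, `r_squared`, `p_value`, `power`, `n`.
#' @export
fit_score_regression <- function(quant, qual, alpha = 0.05) {
  ok <- stats::complete.cases(quant, qual)
  quant <- quant[ok]; qual <- qual[ok]
  n <- length(quant)
  if (n < 3) stop("at least 3 matched points are required")
  if (stats::sd(quant) == 0) stop("quantitative scores are constant: slope undefined")
  fit <- stats::lm(qual ~ quant)
  ct <- stats::cor.test(quant, qual)
  r <- unname(ct$estimate)
  zq <- stats::qnorm(1 - alpha / 2)
  zr <- atanh(min(abs(r), 1 - 1e-12)) * sqrt(n - 3)
  power <- stats::pnorm(zr - zq) + stats::pnorm(-zr - zq)
  list(slope = unname(stats::coef(fit)[2]),
       offset = unname(stats::coef(fit)[1]),
       r = r, r_squared = r^2, p_value = ct$p.value,
       power = power, n = n)
}

#' Leave-one-subject-out decoding of clinical scores
#'
#' For every participant, a regression of qualitative on quantitative score
#' is fitted to all *other* participants' data (movement-level points by
#' default, or participant means) and used to predict the held-out
#' participant's mean qualitative score; the fold error is the absolute
#' prediction error as a percentage of the maximal score.
#'
#' @param scores data.frame with columns `participant`, `quant`, `qual`
#'   (one row per movement x participant, or per participant).
#' @param scale_max maximal qualitative score (default 2).
#' @param level `"movement"` (default; fit on movement-level points) or
#'   `"participant"` (fit on participant means).
#' @return list of class `decoding_result`: `folds` (participant, predicted,
#'   actual, error_pct, offset, slope, r_squared) and `summary`
#'   (mean_error_pct, sd_error_pct, n_folds).
#' @export
loso_decode <- function(scores, scale_max = 2,
                        level = c("movement", "participant")) {
  level <- match.arg(level)
  ps <- unique(scores$participant)
  if (length(ps) < 3) stop("at least 3 participants are required")
  pm <- stats::aggregate(cbind(quant, qual) ~ participant, scores, mean)
  folds <- do.call(rbind, lapply(ps, function(p) {
    train <- if (level == "movement") scores[scores$participant != p, ]
             else pm[pm$participant != p, ]
    fit <- stats::lm(qual ~ quant, data = train)
    held <- pm[pm$participant == p, ]
    pred <- unname(stats::predict(fit, newdata = held))
    ss_tot <- sum((train$qual - mean(train$qual))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
    data.frame(participant = p, predicted = pred, actual = held$qual,
               error_pct = 100 * abs(pred - held$qual) / scale_max,
               offset = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]),
               r_squared = r2)
  }))
  structure(list(
    folds = folds,
    summary = data.frame(mean_error_pct = mean(folds$error_pct),
                         sd_error_pct = stats::sd(folds$error_pct),
                         n_folds = nrow(folds))
  ), class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<decoding_result> %d folds | mean error %.2f +/- %.2f %% of maximal score\n",
              s$n_folds, s$mean_error_pct, s$sd_error_pct))
  invisible(x)
}
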
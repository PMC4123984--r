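test_that("identical trial errors give a zero error curve and k* = 1", {
  res <- min_repetitions(rep(1.5, 6), seed = 1)
  expect_equal(unname(res$error_curve), rep(0, 6))
  expect_equal(res$k_star, 1L)
})

test_that("the two-point error set {0, 2} has bootstrap error exactly 1 at k = 1", {
  # enumeration: draws are 0 or 2 with probability 1/2; (draw - 1)^2 = 1 always
  res <- min_repetitions(c(0, 2), n_draws = 50, seed = 2)
  expect_equal(unname(res$error_curve[1]), 1)
})

test_that("bootstrap error curves converge to the analytic Var/k law", {
  set.seed(3)
  errs <- rgamma(8, shape = 2, rate = 1)
  res <- min_repetitions(errs, n_draws = 1e5, seed = 4)
  pop_var <- mean((errs - mean(errs))^2)   # bootstrap population variance
  for (k in c(1, 2, 4, 8)) {
    expect_lt(abs(res$error_curve[k] - pop_var / k) / (pop_var / k), 0.05)
  }
})

test_that("bootstrap results are bit-reproducible under a fixed seed", {
  errs <- c(0.3, 1.1, 0.8, 2.0, 0.5)
  a <- min_repetitions(errs, seed = 7)
  b <- min_repetitions(errs, seed = 7)
  expect_identical(a$error_curve, b$error_curve)
  expect_identical(a$k_star, b$k_star)
  c_ <- min_repetitions(errs, seed = 8)
  expect_false(identical(a$error_curve, c_$error_curve))
})

test_that("the criterion switch changes the threshold as documented", {
  errs <- c(2, 3, 2.5, 4, 3.5, 2.8)
  hw <- min_repetitions(errs, seed = 5, criterion = "half-width")
  lb <- min_repetitions(errs, seed = 5, criterion = "lower-bound")
  se <- sd(errs) / sqrt(length(errs))
  tq <- qt(0.975, length(errs) - 1)
  expect_equal(hw$threshold, (tq * se)^2, tolerance = 1e-12)
  expect_equal(lb$threshold, mean(errs) - tq * se, tolerance = 1e-12)
  expect_error(min_repetitions(1.0), "2 trials")
})

make_panel <- function(score_fun, n_raters = 30, n_p = 4, n_m = 3) {
  grid <- expand.grid(participant = sprintf("p%d", seq_len(n_p)),
                      movement = sprintf("m%d", seq_len(n_m)),
                      limb = "paretic",
                      rater = sprintf("r%02d", seq_len(n_raters)),
                      stringsAsFactors = FALSE)
  grid$score <- score_fun(grid)
  rating_panel(grid)
}

test_that("unanimous raters need one rater; a perfect model is never matched", {
  unanimous <- make_panel(function(g) ifelse(g$participant == "p1", 2, 1))
  me <- expand.grid(participant = sprintf("p%d", 1:4),
                    movement = sprintf("m%d", 1:3),
                    stringsAsFactors = FALSE)
  me$error <- 0.05
  res <- raters_to_match(unanimous, me, n_draws = 100, seed = 1)
  expect_true(all(res$per_key$k_star == 1))

  set.seed(2)
  noisy <- make_panel(function(g) sample(0:2, nrow(g), replace = TRUE))
  me0 <- me; me0$error <- 0
  res0 <- raters_to_match(noisy, me0, n_draws = 100, seed = 3)
  expect_true(all(is.na(res0$per_key$k_star)))
  expect_equal(res0$summary$n_reached, 0)

  expect_error(raters_to_match(noisy, me[-1, ], seed = 1), "missing key")
})

test_that("model error equal to the variance of an m-rater mean recovers k* = m", {
  # oracle: the rater-error curve is Var_pop/m, so it crosses Var_pop/m0 at m0
  set.seed(4)
  for (m0 in c(2, 5)) {
    panel <- make_panel(function(g) {
      pmin(pmax(round(1 + rnorm(nrow(g), 0, 0.6)), 0), 2)
    }, n_p = 2, n_m = 2)
    e <- panel$entries
    e$key <- paste(e$participant, e$movement)
    me <- unique(e[c("participant", "movement")])
    me$error <- vapply(paste(me$participant, me$movement), function(kk) {
      sc <- e$score[e$key == kk]
      mean((sc - mean(sc))^2) / m0
    }, numeric(1))
    res <- raters_to_match(panel, me, n_draws = 4000, seed = 10 + m0)
    expect_true(all(abs(res$per_key$k_star - m0) <= 1))
  }
})

test_that("ICC is 1 for perfect agreement and decays to 0 with rater noise", {
  raters <- letters[1:7]
  truth <- rep(seq(0, 2, length.out = 12), 2)
  grid <- expand.grid(item = 1:24, rater = raters)
  e <- data.frame(participant = sprintf("p%d", (grid$item - 1) %/% 3 + 1),
                  movement = sprintf("m%d", (grid$item - 1) %% 3 + 1),
                  limb = rep(c("paretic", "nonparetic"), each = 12)[grid$item],
                  rater = grid$rater,
                  score = round(truth[grid$item]))
  perfect <- rating_panel(e)
  icc <- icc_per_rater(perfect)
  expect_equal(icc$icc, rep(1, 7), tolerance = 1e-9)

  # near-infinite noise: one rater's scores unrelated to the items; with 6
  # faithful raters the group mean is dominated by the item truth, so the
  # uninformative rater's ICC collapses
  set.seed(6)
  e2 <- e
  e2$score[e2$rater == "a"] <- sample(0:2, sum(e2$rater == "a"), replace = TRUE)
  icc2 <- icc_per_rater(rating_panel(e2))
  expect_lt(icc2$icc[icc2$rater == "a"], 0.5)
  expect_gt(min(icc2$icc[icc2$rater != "a"]), 0.8)

  flat <- e
  flat$score <- 1
  expect_warning(icc3 <- icc_per_rater(rating_panel(flat)), "undefined")
  expect_true(all(is.na(icc3$icc)))
})

test_that("score regression recovers exact fits and rejects degenerate input", {
  quant <- seq(0.2, 0.9, length.out = 10)
  qual <- 4 * quant - 1.6
  fit <- fit_score_regression(quant, qual)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 4, tolerance = 1e-9)
  expect_equal(fit$offset, -1.6, tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-12)
  expect_equal(fit$power, 1, tolerance = 1e-6)

  expect_error(fit_score_regression(rep(0.5, 10), qual), "constant")
  expect_error(fit_score_regression(quant[1:2], qual[1:2]), "3")
})

test_that("empirical rejection rate matches the Fisher-z power approximation", {
  n <- 30; rho <- 0.45; alpha <- 0.05
  analytic <- {
    zq <- qnorm(1 - alpha / 2)
    pnorm(atanh(rho) * sqrt(n - 3) - zq) + pnorm(-atanh(rho) * sqrt(n - 3) - zq)
  }
  set.seed(8)
  rejections <- replicate(1000, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    cor.test(x, y)$p.value < alpha
  })
  expect_lt(abs(mean(rejections) - analytic), 0.03)
  # and the power reported by the fit agrees with the same formula
  set.seed(9)
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  fit <- fit_score_regression(x, y)
  r <- fit$r
  expect_equal(fit$power,
               pnorm(atanh(abs(r)) * sqrt(n - 3) - qnorm(0.975)) +
                 pnorm(-atanh(abs(r)) * sqrt(n - 3) - qnorm(0.975)),
               tolerance = 1e-9)
})

test_that("leave-one-subject-out decoding is exact on collinear data", {
  tab <- expand.grid(participant = sprintf("p%d", 1:5), movement = 1:4)
  tab$quant <- seq(0.3, 0.9, length.out = nrow(tab))
  tab$qual <- 3.5 * tab$quant - 1.0
  res <- loso_decode(tab)
  expect_equal(res$summary$n_folds, 5)
  expect_equal(res$folds$error_pct, rep(0, 5), tolerance = 1e-9)
  expect_equal(res$folds$slope, rep(3.5, 5), tolerance = 1e-9)
  expect_equal(res$folds$offset, rep(-1.0, 5), tolerance = 1e-9)

  three <- tab[tab$participant %in% c("p1", "p2", "p3"), ]
  expect_equal(loso_decode(three)$summary$n_folds, 3)
  expect_error(loso_decode(tab[tab$participant %in% c("p1", "p2"), ]), "3")
})

test_that("decoding error under known noise matches the OLS prediction-error law", {
  # design: fixed quant values, qual = a*quant + b + N(0, sigma) per point;
  # analytic E|fold error| from the OLS prediction variance at the held-out
  # participant's mean quant, plus the noise in that participant's own mean
  n_p <- 6; n_m <- 5; sigma <- 0.3; a <- 3; b <- -1
  tab0 <- expand.grid(participant = sprintf("p%d", 1:n_p), movement = 1:n_m)
  set.seed(12)
  tab0$quant <- runif(nrow(tab0), 0.3, 0.95)
  pm_quant <- tapply(tab0$quant, tab0$participant, mean)

  analytic_fold_sd <- vapply(sprintf("p%d", 1:n_p), function(p) {
    tr <- tab0[tab0$participant != p, ]
    x <- tr$quant; n <- length(x)
    x0 <- pm_quant[[p]]
    pred_var <- sigma^2 * (1 / n + (x0 - mean(x))^2 / sum((x - mean(x))^2))
    sqrt(pred_var + sigma^2 / n_m)   # + noise in the held-out participant mean
  }, numeric(1))
  analytic_mean_err_pct <- mean(sqrt(2 / pi) * analytic_fold_sd) / 2 * 100

  set.seed(13)
  mc <- replicate(200, {
    tab <- tab0
    tab$qual <- a * tab$quant + b + rnorm(nrow(tab), 0, sigma)
    loso_decode(tab)$summary$mean_error_pct
  })
  expect_lt(abs(mean(mc) - analytic_mean_err_pct) / analytic_mean_err_pct, 0.25)
})
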
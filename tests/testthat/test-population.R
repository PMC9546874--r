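test_that("thresholds split a clear bimodal sample at the density crossing", {
  set.seed(3)
  v <- c(rnorm(1000, 0.2, 0.05), rnorm(1000, 1.0, 0.1))
  # density-crossing oracle of the generating mixture: ~0.47
  tm_g <- fit_threshold(v, "gmm2")
  expect_gt(tm_g$threshold, 0.4)
  expect_lt(tm_g$threshold, 0.8)
  # otsu lands in the inter-mode valley
  tm_o <- fit_threshold(v, "otsu")
  expect_gt(tm_o$threshold, 0.3)
  expect_lt(tm_o$threshold, 0.8)
  tm <- fit_threshold(v, "manual", value = 0.6)
  expect_equal(tm$threshold, 0.6)
  expect_error(fit_threshold(rep(1, 100), "otsu"), "constant")
  expect_error(fit_threshold(rnorm(5), "otsu"), "at least 10")
})

test_that("positive fractions behave at the extremes and under monotone maps", {
  df <- tibble::tibble(t = rep(c(1, 2), each = 5),
                       value = c(rep(2, 5), rep(0, 5)))
  fp <- fraction_positive_timecourse(df, 1)
  expect_equal(fp$percent, c(100, 0))
  # polarity flip for "inactive"-type channels
  fp2 <- fraction_positive_timecourse(df, 1, polarity = "below")
  expect_equal(fp2$percent, c(0, 100))
  # equivariance under a strictly increasing transform
  set.seed(8)
  df3 <- tibble::tibble(t = rep(1:3, each = 50), value = rnorm(150))
  a <- fraction_positive_timecourse(df3, 0.3)
  df4 <- dplyr::mutate(df3, value = exp(value))
  b <- fraction_positive_timecourse(df4, exp(0.3))
  expect_equal(a$percent, b$percent)
})

test_that("CDK4/6-positive percentage rises through the time course", {
  p <- calib_paper_params()
  ts <- simulate_population(p, n_cells = 1500, seed = 17)
  df <- tibble::as_tibble(ts)
  df$corr <- correct_cdk46(df$r46_obs, df$r2_obs, p$crosstalk_rho)
  sub <- df[df$t %in% seq(0, 14, by = 2), c("t", "corr")]
  fp <- fraction_positive_timecourse(
    tibble::tibble(t = sub$t, value = sub$corr), 0.3)
  expect_true(all(diff(fp$percent) > -3))
  expect_gt(fp$percent[nrow(fp)], fp$percent[1] + 10)
})

test_that("sigmoid fits recover noiseless parameters to machine precision", {
  sig <- function(t, lo, up, t50, sl) lo + (up - lo) / (1 + exp(-sl * (t - t50)))
  set.seed(12)
  for (i in 1:50) {
    lo <- runif(1, 0, 20); up <- lo + runif(1, 20, 80)
    t50 <- runif(1, 3, 11); sl <- runif(1, 0.4, 3)
    t <- seq(0, 14, by = 1)
    f <- fit_sigmoid(t, sig(t, lo, up, t50, sl))
    expect_lt(f$rss, 1e-9)
  }
  # noised binomial sampling keeps t50 within half an hour
  t <- seq(0, 14, by = 1)
  truth <- sig(t, 5, 95, 7, 1.2)
  set.seed(5)
  p_obs <- 100 * rbinom(length(t), 500, truth / 100) / 500
  fn <- fit_sigmoid(t, p_obs)
  expect_lt(abs(fn$t50 - 7), 0.5)
  # constant response flags a degenerate fit
  fd <- fit_sigmoid(t, rep(50, length(t)))
  expect_true(fd$degenerate)
})

test_that("activity maps summarize binary markers as percentages", {
  set.seed(9)
  x <- runif(4000, 0, 2.5); y <- runif(4000, 0, 2.5)
  am1 <- activity_map(x, y, rep(1, 4000), bins = 10)
  expect_true(all(am1$stat[!is.na(am1$stat)] == 100))
  # independent marker: every unmasked bin near 50%
  mk <- rbinom(4000, 1, 0.5)
  am2 <- activity_map(x, y, mk, bins = 5, min_n = 30)
  expect_true(all(abs(am2$stat[!is.na(am2$stat)] - 50) < 20))
  # totals: counts plus dropped points equal the input length
  am3 <- activity_map(x, y + 2, mk, bins = 5)
  expect_equal(sum(am3$n) + attr(am3, "n_dropped"), 4000)
  expect_equal(nrow(activity_map(numeric(0), numeric(0), numeric(0))), 0)
})

test_that("activity maps recover the generative Rb-positivity rule", {
  p <- calib_paper_params()
  ts <- simulate_population(p, n_cells = 3000, seed = 19)
  df <- tibble::as_tibble(ts)
  at14 <- df[df$frame == max(df$frame), ]
  tr <- cell_truth(ts)
  corr <- correct_cdk46(at14$r46_obs, at14$r2_obs, p$crosstalk_rho)
  prb <- corr >= p$theta_rb | tr$committed
  am <- activity_map(corr, at14$r2_obs, prb, bins = 10, limits = c(0, 2),
                     min_n = 10)
  hi <- am[!is.na(am$stat) & am$x_lo >= 0.8, ]
  lo <- am[!is.na(am$stat) & am$x_hi <= 0.2 & am$y_hi <= 0.4, ]
  expect_true(all(hi$stat >= 90))
  expect_true(all(lo$stat <= 10))
})

test_that("phase gating recovers a constructed 2N/4N + EdU mixture", {
  set.seed(21)
  n <- 3000
  phase <- sample(c("G0/G1", "S", "G2/M"), n, replace = TRUE,
                  prob = c(0.6, 0.25, 0.15))
  hoechst <- ifelse(phase == "G0/G1", rnorm(n, 100, 8),
                    ifelse(phase == "G2/M", rnorm(n, 200, 12),
                           rnorm(n, 150, 20)))
  edu <- ifelse(phase == "S", rnorm(n, 50, 5), rnorm(n, 5, 2))
  g <- gate_phases(hoechst, edu)
  expect_lt(abs(mean(g$phase == "S") - mean(phase == "S")), 0.02)
  expect_gt(mean(g$phase == phase), 0.95)
  # all EdU-negative, one band: everything G0/G1
  g2 <- gate_phases(rnorm(200, 100, 5), rnorm(200, 5, 1),
                    edu_threshold = 30)
  expect_true(all(g2$phase == "G0/G1"))
  expect_equal(nrow(gate_phases(numeric(0), numeric(0))), 0)
})

test_that("welch_ttest matches the closed-form arithmetic oracle", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  # hand computation: means 3 and 4, var 2.5 each, se = 1, t = -1, df = 8
  res <- welch_ttest(a, b)
  expect_equal(res$t, -1)
  expect_equal(res$df, 8)
  expect_equal(res$p, 2 * pt(-1, 8))
  # identical samples
  same <- welch_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # symmetry: swap negates t, preserves p
  sw <- welch_ttest(b, a)
  expect_equal(sw$t, -res$t)
  expect_equal(sw$p, res$p)
  # degenerate zero-variance samples
  dg <- welch_ttest(rep(1, 3), rep(1, 4))
  expect_true(dg$flag_degenerate)
  expect_equal(dg$p, 1)
  # power sanity
  set.seed(33)
  ps <- welch_ttest(rnorm(100), rnorm(100, 1))
  expect_lt(ps$p, 1e-6)
})
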
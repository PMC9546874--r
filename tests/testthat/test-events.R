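test_that("detect_onset follows the threshold + persistence rule", {
  t <- seq(0, 20, by = 0.2)
  expect_true(is.na(detect_onset(rep(0.1, length(t)), t, 0.5, 3)))
  # clean step at frame 41 (t = 8.0 h)
  x <- c(rep(0, 40), rep(1, length(t) - 40))
  expect_equal(detect_onset(x, t, 0.5, 3), 8.0)
  # a 2-frame blip does not count with w = 3
  y <- rep(0, length(t)); y[10:11] <- 1
  expect_true(is.na(detect_onset(y, t, 0.5, 3)))
  expect_equal(detect_onset(y, t, 0.5, 2), t[10])
  expect_error(detect_onset(1:3, 1:3, 0.5, w = 10), "persistence")
})

test_that("terminal truncated runs count only with censoring-aware calling", {
  t <- seq(0, 2, by = 0.2)
  x <- rep(0, length(t)); x[(length(t) - 1):length(t)] <- 1
  expect_true(is.na(detect_onset(x, t, 0.5, 3)))
  expect_equal(detect_onset(x, t, 0.5, 3, tail_w = 2), t[length(t) - 1])
})

test_that("detect_onset is monotone under positive offsets", {
  set.seed(10)
  t <- seq(0, 14, by = 0.2)
  for (i in 1:25) {
    x <- cumsum(rnorm(length(t), 0.02, 0.05))
    o1 <- detect_onset(x, t, 0.5, 3)
    o2 <- detect_onset(x + 0.2, t, 0.5, 3)
    if (!is.na(o1)) {
      expect_false(is.na(o2))
      expect_lte(o2, o1)
    }
  }
})

test_that("call_events classifies an all-quiescent cohort as CDK4/6-low", {
  p <- calib_paper_params(overrides = list(p_active = 0))
  ts <- simulate_population(p, n_cells = 60, seed = 3)
  ev <- call_events(ts)
  expect_true(all(ev$class46 == "low"))
  expect_true(all(is.na(ev$onset2)))
})

test_that("CDK4/6-high fraction matches the generative activation rate", {
  p <- calib_paper_params()
  ts <- simulate_population(p, n_cells = 2000, seed = 13)
  ev <- call_events(ts)
  tr <- cell_truth(ts)
  expect_lt(abs(mean(ev$class46 == "high") - mean(tr$is_active46)), 0.03)
  # among active cells, detected onsets sit within 2 frames of truth
  j <- dplyr::inner_join(ev, tr, by = "cell_id")
  j <- j[!is.na(j$onset46) & !is.na(j$onset46_true), ]
  lat <- j$onset46 - j$onset46_true
  expect_gt(mean(abs(lat) <= 2 * p$dt + 0.3), 0.95)
  # detected onset ordering mirrors the truth ordering
  both <- !is.na(j$onset46) & !is.na(j$onset2)
  expect_gt(mean(j$onset2[both] >= j$onset46[both]), 0.99)
})

test_that("fate classification reproduces truth labels without noise", {
  p <- calib_paper_params(overrides = list(noise_sd = 0, horizon = 22))
  pert <- perturbation_spec("rapid_inhibitor", t_treat = 11)
  ts <- simulate_population(p, pert, n_cells = 800, seed = 9)
  cf <- classify_fate(ts, t_treat = 11)
  tr <- cell_truth(ts)
  j <- dplyr::inner_join(cf, tr, by = "cell_id")
  j <- j[j$fate %in% c("inc", "low"), ]
  expect_gt(nrow(j), 20)
  expect_equal(mean(j$fate == j$outcome_true), 1)
})

test_that("trivial monotone traces get the expected fates", {
  t <- seq(0, 22, by = 0.2)
  rise <- tibble::tibble(cell_id = 1, t = t,
                         cdk46_corrected = 1, cdk2 = pmin(0.7 + 0.1 * t, 2.4))
  fall <- tibble::tibble(cell_id = 2, t = t,
                         cdk46_corrected = 1,
                         cdk2 = pmax(1 - 0.15 * pmax(t - 11, 0), 0.05))
  cf <- classify_fate(dplyr::bind_rows(rise, fall), t_treat = 11)
  expect_equal(cf$fate[cf$cell_id == 1], "inc")
  expect_equal(cf$fate[cf$cell_id == 2], "low")
  expect_error(classify_fate(rise, t_treat = 21), "window2")
})

test_that("alignment at event time zero returns the pointwise mean", {
  tt <- seq(0, 5, by = 0.5)
  nt <- length(tt)
  df <- tibble::tibble(
    cell_id = rep(1:3, each = nt), t = rep(tt, 3),
    cdk46_corrected = 0, cdk2 = rep(c(1, 2, 3), each = nt))
  ev0 <- tibble::tibble(cell_id = 1:3, event_time = 0)
  al <- align_and_summarize(df, ev0, "cdk2")
  expect_equal(al$offset, tt)
  expect_equal(al$mean, rep(2, nt))
  expect_true(all(al$n == 3))
  # identical traces, identical onsets: mean = trace, zero CI width
  df2 <- tibble::tibble(cell_id = rep(1:2, each = nt), t = rep(tt, 2),
                        cdk46_corrected = 0, cdk2 = rep(sin(tt), 2))
  al2 <- align_and_summarize(df2, tibble::tibble(cell_id = 1:2,
                                                 event_time = 0), "cdk2")
  expect_equal(al2$mean, sin(tt))
  expect_true(all(al2$ci_half == 0))
  # no aligned cells -> empty summary
  al3 <- align_and_summarize(df, tibble::tibble(cell_id = 1:3,
                                                event_time = NA_real_))
  expect_equal(nrow(al3), 0)
})

test_that("aligned CDK2 rises after the CDK4/6 activation event", {
  p <- calib_paper_params()
  ts <- simulate_population(p, n_cells = 600, seed = 21)
  ev <- call_events(ts)
  al <- align_and_summarize(
    ts, tibble::tibble(cell_id = ev$cell_id, event_time = ev$onset46),
    "cdk2")
  m0 <- al$mean[al$offset == 0]
  expect_lt(m0, 0.3)     # near-baseline CDK2 at CDK4/6-on
  nxt <- al[al$offset > 0 & al$offset <= 3, ]
  expect_true(all(diff(nxt$mean) > -0.02))  # rising over the next 3 h
  expect_gt(nxt$mean[nrow(nxt)], m0 + 0.1)
})

test_that("commitment boundary recovers a known logistic boundary", {
  set.seed(101)
  x <- runif(1000, 0, 2)
  pr <- plogis((x - 0.8) * 8)
  y <- ifelse(rbinom(1000, 1, pr) == 1, "inc", "low")
  b <- estimate_commitment_boundary(x, y, n_boot = 200, seed = 1)
  expect_false(b$separation)
  expect_lt(abs(b$boundary - 0.8), 0.05)
  expect_true(b$ci[1] < b$boundary & b$boundary < b$ci[2])
})

test_that("boundary estimator error shrinks with sample size", {
  err <- sapply(c(200, 2000), function(n) {
    mean(sapply(1:20, function(s) {
      set.seed(1000 + s)
      x <- runif(n, 0, 2)
      y <- ifelse(rbinom(n, 1, plogis((x - 0.8) * 6)) == 1, "inc", "low")
      abs(estimate_commitment_boundary(x, y, n_boot = 0, seed = s)$boundary -
            0.8)
    }))
  })
  expect_lt(err[2], err[1])
})

test_that("separated data report the flagged midpoint", {
  b <- estimate_commitment_boundary(c(0.2, 0.4, 1.6, 1.8),
                                    c("low", "low", "inc", "inc"))
  expect_true(b$separation)
  expect_equal(b$boundary, 1.0)
  expect_error(estimate_commitment_boundary(c(1, 2), c("inc", "inc")),
               "both fates")
})

test_that("inactivation delay measures a step-down immediately", {
  t <- seq(0, 20, by = 0.2)
  x <- ifelse(t < 10, 1.2, 0.05)
  expect_equal(inactivation_delay(x, t, t_treat = 10), 0)
  expect_true(is.na(inactivation_delay(rep(1, length(t)), t, 10)))
})
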
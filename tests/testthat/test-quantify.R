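test_that("uniform regions measure value minus background", {
  nx <- 60; ny <- 60
  mask <- disk_mask(cbind(30, 30), 6, nx, ny)
  reg <- segment_regions(mask, cal = 1)
  img <- matrix(5, nx, ny)
  idx <- (reg$y - 1) * nx + reg$x
  img[idx] <- 12
  m <- measure_regions(list(ch = img), reg)
  expect_equal(m$bg, 5)
  expect_equal(m$nuc_mean, 7)
  expect_equal(m$ring_mean, 7)
  expect_false(any(m$flag_no_ring))
})

test_that("a cell with a fully excluded ring is flagged, not dropped", {
  nx <- 60; ny <- 60
  mask <- disk_mask(cbind(30, 30), 6, nx, ny)
  reg <- segment_regions(mask, cal = 1)
  reg <- reg[reg$region != "ring", ]
  m <- measure_regions(list(ch = matrix(1, nx, ny)), reg)
  expect_equal(nrow(m), 1)
  expect_true(m$flag_no_ring)
  expect_true(is.na(m$ring_mean))
})

test_that("ktr_activity is the ring/nucleus ratio with guarded domain", {
  expect_equal(ktr_activity(2, 2), 1)
  expect_equal(ktr_activity(2, 0), 0)
  expect_equal(ktr_activity(c(2, 4), c(1, 2)), c(0.5, 0.5))
  expect_error(ktr_activity(0, 1), "nuc_mean")
  # invariance under a global multiplicative gain
  expect_equal(ktr_activity(3 * 2, 3 * 1.2), ktr_activity(2, 1.2))
})

test_that("estimate_crosstalk fits an exact line and flags degeneracy", {
  d <- tibble::tibble(r2_obs = seq(0, 2, length.out = 20),
                      r46_obs = 0.5 * seq(0, 2, length.out = 20))
  m <- estimate_crosstalk(d)
  expect_equal(m$rho, 0.5, tolerance = 1e-10)
  expect_equal(m$intercept, 0, tolerance = 1e-10)
  expect_equal(m$residual_sd, 0, tolerance = 1e-8)
  expect_error(estimate_crosstalk(tibble::tibble(r2_obs = rep(1, 5),
                                                 r46_obs = rnorm(5))),
               "singular")
  td <- generics::tidy(m)
  expect_equal(td$estimate[td$term == "rho"], 0.5, tolerance = 1e-10)
})

test_that("crosstalk slope recovers the generative coefficient", {
  cp <- simulate_calibration_pairs(rho = 0.35, n = 500, noise_sd = 0.05,
                                   seed = 7)
  m <- estimate_crosstalk(cp)
  expect_lt(abs(m$rho - 0.35), 0.02)
})

test_that("crosstalk estimation error shrinks with n", {
  err <- sapply(c(100, 1000, 10000), function(n) {
    mean(sapply(1:20, function(s) {
      cp <- simulate_calibration_pairs(rho = 0.35, n = n, noise_sd = 0.1,
                                       seed = 100 + s)
      abs(estimate_crosstalk(cp)$rho - 0.35)
    }))
  })
  expect_true(all(diff(err) < 0))
})

test_that("correct_cdk46 subtracts the proportional term only", {
  expect_equal(correct_cdk46(1.0, 0, 0.7), 1.0)
  expect_equal(correct_cdk46(1.0, 1.0, 0.35), 0.65)
  expect_equal(correct_cdk46(0.35, 1.0, 0.35), 0)
  # linear in both arguments; intercept never subtracted
  m <- estimate_crosstalk(tibble::tibble(r2_obs = c(0, 1, 2),
                                         r46_obs = c(0.2, 0.6, 1.0)))
  expect_equal(correct_cdk46(1, 1, m), 1 - m$rho)
  a <- correct_cdk46(2, 3, 0.35); b <- correct_cdk46(1, 1, 0.35)
  expect_equal(correct_cdk46(2 + 1, 3 + 1, 0.35), a + b)
})

test_that("degron_level floors a background-only region at zero", {
  nx <- 40; ny <- 40
  mask <- disk_mask(cbind(20, 20), 5, nx, ny)
  reg <- segment_regions(mask, cal = 1)
  d <- degron_level(matrix(3, nx, ny), reg)
  expect_equal(d$degron, 0)
})

test_that("top-hat puncta counting matches constructed spot fields", {
  nx <- 120; ny <- 120
  mask <- disk_mask(cbind(60, 60), 8, nx, ny)
  cfg <- segmentation_config()
  reg <- segment_regions(mask, cal = 1, wholecell = TRUE)
  # blank image: nothing anywhere
  blank <- matrix(10, nx, ny)
  f0 <- fish_puncta_per_cell(blank, reg, cfg, cal = 1, threshold = 5)
  expect_equal(f0$puncta_pixels, 0)
  expect_equal(f0$puncta_count, 0)
  # five well-separated spots inside the whole-cell region
  img <- matrix(10, nx, ny)
  centers <- cbind(c(45, 60, 75, 60, 60), c(60, 45, 60, 75, 60))
  for (i in 1:5) img[centers[i, 1], centers[i, 2]] <- 200
  f5 <- fish_puncta_per_cell(img, reg, cfg, cal = 1, threshold = 50)
  expect_equal(f5$puncta_count, 5)
  expect_gte(f5$puncta_pixels, 5)
  # constant offset leaves the top-hat result unchanged
  f5b <- fish_puncta_per_cell(img + 500, reg, cfg, cal = 1, threshold = 50)
  expect_equal(f5b$puncta_pixels, f5$puncta_pixels)
  expect_error(fish_puncta_per_cell(matrix(1, 4, 4), reg,
                                    segmentation_config(
                                      fish_kernel_radius_um = 4),
                                    cal = 1),
               "kernel")
})

test_that("rendered FISH fields give counts monotone in the truth", {
  nx <- 220; ny <- 220
  centers <- as.matrix(expand.grid(c(40, 110, 180), c(40, 110, 180)))
  mask <- disk_mask(centers, 7, nx, ny)
  reg <- whole_cell_regions(mask, segmentation_config(wholecell_reach_um = 18),
                            cal = 1)
  set.seed(13)
  counts <- tibble::tibble(cell_id = 1:9, mrna_true = rpois(9, 20))
  im <- imaging_params(field_px = c(nx, ny), seed = 13, read_noise = 2)
  ff <- render_fish_field(counts, reg, im, spot_sigma_px = 1.5)
  f <- fish_puncta_per_cell(ff$image, reg, segmentation_config(), cal = 1)
  j <- dplyr::inner_join(f, counts, by = "cell_id")
  expect_gte(cor(j$puncta_pixels, j$mrna_true, method = "spearman"), 0.9)
})
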
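test_that("illumination correction inverts a known quadratic bias", {
  nx <- 120; ny <- 100
  u <- matrix(seq_len(nx) / nx * 2 - 1, nx, ny)
  v <- matrix(rep(seq_len(ny) / ny * 2 - 1, each = nx), nx, ny)
  bias <- 1 + 0.3 * u - 0.2 * v + 0.15 * u^2
  flat <- matrix(100, nx, ny)
  # known bias: exact round trip
  corr <- correct_illumination(flat * bias, bias = bias)
  expect_lt(stats::sd(corr) / mean(corr), 1e-10)
  expect_equal(mean(corr), mean(flat * bias), tolerance = 1e-10)
  # estimated bias: flat within 2% RMS
  set.seed(2)
  noisy <- flat * bias + matrix(rnorm(nx * ny, 0, 1), nx, ny)
  corr2 <- correct_illumination(noisy)
  expect_lt(stats::sd(corr2) / mean(corr2), 0.02)
  # constant bias is the identity
  corr3 <- correct_illumination(flat, bias = matrix(2, nx, ny))
  expect_equal(corr3, flat)
  expect_error(correct_illumination(flat, bias = matrix(-1, nx, ny)),
               "positive")
})

test_that("nucleus segmentation finds disjoint disks and splits necks", {
  expect_equal(max(segment_nuclei(matrix(0, 50, 50), cal = 1)), 0)
  nx <- 180; ny <- 140
  centers <- as.matrix(expand.grid(c(40, 90, 140), c(40, 100)))
  truth <- disk_mask(centers, 9, nx, ny)
  img <- matrix(10, nx, ny) + 100 * (truth > 0)
  set.seed(4)
  img <- img + matrix(rnorm(nx * ny, 0, 2), nx, ny)
  mask <- segment_nuclei(img, cal = 1)
  expect_equal(max(mask), 6)
  for (k in 1:6) {
    a <- mask == k
    best <- max(sapply(1:6, function(j) {
      b <- truth == j
      sum(a & b) / sum(a | b)
    }))
    expect_gte(best, 0.9)
  }
  # two overlapping disks split by the watershed
  t2 <- disk_mask(rbind(c(55, 60), c(75, 60)), 11, 130, 120)
  img2 <- matrix(5, 130, 120) + 80 * (t2 > 0)
  m2 <- segment_nuclei(img2, cal = 1)
  expect_equal(max(m2), 2)
})

test_that("ring regions equal the brute-force distance-rule oracle", {
  cal <- 0.65
  nx <- 96; ny <- 96
  mask <- disk_mask(cbind(48, 48), 5 / cal, nx, ny)
  ring <- cytoplasmic_ring(mask, segmentation_config(), cal)
  oracle <- brute_ring(mask, cal)
  expect_identical(region_pixel_idx(ring, "ring", 1, nx),
                   sort(oracle[["1"]]))
  # two nuclei close enough that exclusion zones overlap
  mask2 <- disk_mask(rbind(c(30, 48), c(62, 48)), 4 / cal, nx, ny)
  ring2 <- cytoplasmic_ring(mask2, segmentation_config(), cal)
  oracle2 <- brute_ring(mask2, cal)
  for (k in 1:2) {
    expect_identical(region_pixel_idx(ring2, "ring", k, nx),
                     sort(oracle2[[as.character(k)]]))
  }
  # partial rings stay disjoint
  i1 <- region_pixel_idx(ring2, "ring", 1, nx)
  i2 <- region_pixel_idx(ring2, "ring", 2, nx)
  expect_length(intersect(i1, i2), 0)
})

test_that("ring at the field edge stays in bounds", {
  cal <- 1
  mask <- disk_mask(cbind(6, 6), 5, 64, 64)
  ring <- cytoplasmic_ring(mask, segmentation_config(), cal)
  expect_true(all(ring$x >= 1 & ring$x <= 64 & ring$y >= 1 & ring$y <= 64))
  oracle <- brute_ring(mask, cal)
  expect_identical(region_pixel_idx(ring, "ring", 1, 64),
                   sort(oracle[["1"]]))
})

test_that("whole-cell regions equal the nearest-nucleus oracle", {
  cal <- 0.65
  nx <- 128; ny <- 128
  # two nuclei ~40 um apart: split along the equidistant line
  mask <- disk_mask(rbind(c(35, 64), c(96, 64)), 6, nx, ny)
  wc <- whole_cell_regions(mask, segmentation_config(), cal)
  oracle <- brute_wholecell(mask, cal)
  for (k in 1:2) {
    expect_identical(region_pixel_idx(wc, "wholecell", k, nx),
                     sort(oracle[[as.character(k)]]))
  }
  i1 <- region_pixel_idx(wc, "wholecell", 1, nx)
  i2 <- region_pixel_idx(wc, "wholecell", 2, nx)
  expect_length(intersect(i1, i2), 0)
  # dense field: full coverage within reach, no overlaps
  centers <- as.matrix(expand.grid(c(25, 64, 103), c(25, 64, 103)))
  mask3 <- disk_mask(centers, 5, nx, ny)
  wc3 <- whole_cell_regions(mask3, segmentation_config(), cal)
  oracle3 <- brute_wholecell(mask3, cal)
  all_pix <- sort(unlist(lapply(1:9, function(k)
    region_pixel_idx(wc3, "wholecell", k, nx))))
  expect_identical(all_pix, sort(unname(unlist(oracle3))))
  expect_equal(anyDuplicated(all_pix), 0)
})

test_that("region geometry ignores image intensity rescaling", {
  cal <- 1
  mask <- disk_mask(rbind(c(30, 30), c(70, 60)), 6, 100, 90)
  set.seed(5)
  img <- matrix(runif(9000, 10, 20), 100, 90)
  r1 <- cytoplasmic_ring(mask, segmentation_config(background_floor = 0),
                         cal, intensity = img)
  r2 <- cytoplasmic_ring(mask, segmentation_config(background_floor = 0),
                         cal, intensity = img * 7)
  expect_identical(r1$x, r2$x)
  expect_identical(r1$y, r2$y)
  wc <- whole_cell_regions(mask, segmentation_config(), cal)
  # rings never intersect any nucleus; wholecell contains its nucleus
  nuc_idx <- which(as.vector(mask) > 0)
  expect_length(intersect((r1$y - 1) * 100 + r1$x, nuc_idx), 0)
  for (k in 1:2) {
    expect_true(all(which(as.vector(mask) == k) %in%
                      region_pixel_idx(wc, "wholecell", k, 100)))
  }
})

test_that("the ring background rule drops dim pixels", {
  cal <- 1
  mask <- disk_mask(cbind(40, 40), 6, 80, 80)
  img <- matrix(100, 80, 80)
  # make the left half of the field dark (below any sensible floor)
  img[1:40, ] <- 0
  ring <- cytoplasmic_ring(mask, segmentation_config(background_floor = 50),
                           cal, intensity = img)
  expect_true(all(ring$x > 40))
})
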
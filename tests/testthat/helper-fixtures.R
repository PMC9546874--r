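# Shared fixtures and independent oracles.

# disk-shaped nucleus mask on an [nx x ny] field
disk_mask <- function(centers, r_px, nx, ny, labels = seq_len(nrow(centers))) {
  m <- matrix(0L, nx, ny)
  for (i in seq_len(nrow(centers))) {
    xs <- pmax(1, floor(centers[i, 1] - r_px)):pmin(nx, ceiling(centers[i, 1] + r_px))
    ys <- pmax(1, floor(centers[i, 2] - r_px)):pmin(ny, ceiling(centers[i, 2] + r_px))
    g <- expand.grid(x = xs, y = ys)
    keep <- (g$x - centers[i, 1])^2 + (g$y - centers[i, 2])^2 <= r_px^2
    m[cbind(g$x[keep], g$y[keep])] <- labels[i]
  }
  m
}

# brute-force per-pixel distance of every pixel to each labelled nucleus:
# Euclidean distance between pixel centres to the nearest nucleus pixel
# (0 inside the nucleus). Returns [npix x nlab].
brute_distance_stack <- function(mask) {
  labels <- sort(unique(mask[mask > 0]))
  nx <- nrow(mask); ny <- ncol(mask)
  px <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  d <- matrix(NA_real_, nrow(px), length(labels))
  for (i in seq_along(labels)) {
    nxs <- row(mask)[mask == labels[i]]
    nys <- col(mask)[mask == labels[i]]
    dd <- rep(Inf, nrow(px))
    for (j in seq_along(nxs)) {
      dd <- pmin(dd, (px$x - nxs[j])^2 + (px$y - nys[j])^2)
    }
    d[, i] <- sqrt(dd)
  }
  list(d = d, labels = labels)
}

# brute-force ring rule: 2-10 um band around nucleus k, excluding any pixel
# within excl of another nucleus or inside any nucleus
brute_ring <- function(mask, cal, rin_um = 2, rout_um = 10, excl_um = 10) {
  bs <- brute_distance_stack(mask)
  rin <- rin_um / cal; rout <- rout_um / cal; excl <- excl_um / cal
  in_nuc <- as.vector(mask) > 0
  out <- list()
  for (i in seq_along(bs$labels)) {
    dk <- bs$d[, i]
    others <- bs$d[, -i, drop = FALSE]
    near_other <- if (ncol(others)) apply(others, 1, min) <= excl else FALSE
    out[[i]] <- which(dk >= rin & dk <= rout & !in_nuc & !near_other)
  }
  names(out) <- bs$labels
  out
}

# brute-force whole-cell rule: within reach, nearest nucleus wins (ties to
# lower label), plus own nucleus
brute_wholecell <- function(mask, cal, reach_um = 50) {
  bs <- brute_distance_stack(mask)
  reach <- reach_um / cal
  nearest <- apply(bs$d, 1, which.min)   # first minimum = lower label
  dmin <- bs$d[cbind(seq_len(nrow(bs$d)), nearest)]
  maskv <- as.vector(mask)
  out <- list()
  for (i in seq_along(bs$labels)) {
    out[[i]] <- which((nearest == i & dmin <= reach) | maskv == bs$labels[i])
  }
  names(out) <- bs$labels
  out
}

region_pixel_idx <- function(regions, which_region, cell, nx) {
  r <- regions[regions$region == which_region & regions$cell_id == cell, ]
  sort((r$y - 1L) * as.integer(nx) + r$x)
}

# all permutations of 1..n (for assignment oracles, n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Small rendered movie shared by tracking / round-trip acceptance tests.
# All cells activate (p_active = 1) so the rendered cohort spans the full
# CDK2 activity range within the 60-frame window.
make_test_movie <- function(n_cells = 20, n_frames = 60, seed = 11,
                            field = c(320, 260)) {
  p <- calib_paper_params(overrides = list(p_active = 1))
  ts <- simulate_population(p, n_cells = n_cells, seed = seed)
  df <- dplyr::filter(tibble::as_tibble(ts), frame <= n_frames)
  im <- imaging_params(field_px = field, seed = seed)
  list(movie = render_movie(df, im), traces = df, imaging = im, params = p)
}

# match per-frame detections to ground-truth cells by nearest centre
match_to_truth <- function(dets, positions, max_px = 10) {
  purrr::map_dfr(seq_len(nrow(dets)), function(i) {
    pos <- positions[positions$frame == dets$frame[i], ]
    d2 <- (pos$x - dets$x[i])^2 + (pos$y - dets$y[i])^2
    j <- which.min(d2)
    tibble::tibble(frame = dets$frame[i], label = dets$label[i],
                   true_cell = if (d2[j] <= max_px^2) pos$cell_id[j]
                               else NA_integer_)
  })
}
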
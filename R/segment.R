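#' Segmentation geometry configuration
#'
#' Houses the measurement-region geometry, in micrometres: the cytoplasmic
#' ring spans 2-10 um outside the nuclear mask, pixels within 10 um of
#' another nucleus are excluded, whole-cell regions reach up to 50 um from
#' the nucleus while never overlapping a neighbour's territory, and the FISH
#' top-hat kernel has a 4 um radius.
#'
#' @param ring_inner_um,ring_outer_um Ring inner/outer distance from the
#'   nuclear mask, um.
#' @param neighbor_exclusion_um Pixels within this distance of another
#'   nucleus are excluded from the ring.
#' @param wholecell_reach_um Maximum whole-cell reach from the nucleus, um.
#' @param min_nucleus_area_um2 Nuclei smaller than this are discarded.
#' @param background_floor Optional absolute intensity floor for ring
#'   pixels; when `NULL` it is derived from the background as
#'   `median + 2 * mad`.
#' @param fish_kernel_radius_um Top-hat structuring-element radius, um.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(ring_inner_um = 2, ring_outer_um = 10,
                                neighbor_exclusion_um = 10,
                                wholecell_reach_um = 50,
                                min_nucleus_area_um2 = 20,
                                background_floor = NULL,
                                fish_kernel_radius_um = 4) {
  if (ring_inner_um >= ring_outer_um)
    stop("ring_inner_um must be smaller than ring_outer_um", call. = FALSE)
  structure(list(ring_inner_um = ring_inner_um,
                 ring_outer_um = ring_outer_um,
                 neighbor_exclusion_um = neighbor_exclusion_um,
                 wholecell_reach_um = wholecell_reach_um,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 background_floor = background_floor,
                 fish_kernel_radius_um = fish_kernel_radius_um),
            class = "segmentation_config")
}

#' Correct multiplicative illumination bias
#'
#' Divides the image by a multiplicative bias surface normalized to unit
#' mean. If no surface is supplied, one is estimated by fitting a quadratic
#' in the pixel coordinates to coarse-grid background quantiles (10th
#' percentile per block). The output mean equals the input mean.
#'
#' @param image 2D intensity matrix.
#' @param bias Optional known bias surface (same dimensions, all positive).
#' @param grid Number of blocks per axis for the background-quantile fit.
#' @return Corrected image of the same dimensions.
#' @export
correct_illumination <- function(image, bias = NULL, grid = 8L) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (is.null(bias)) {
    bias <- fit_bias_surface(image, grid)
  } else {
    stopifnot(all(dim(bias) == dim(image)))
    if (any(bias <= 0)) stop("bias surface must be strictly positive",
                             call. = FALSE)
  }
  out <- image / (bias / mean(bias))
  out * (mean(image) / mean(out))
}

# quadratic surface through per-block low quantiles of the image
fit_bias_surface <- function(image, grid = 8L) {
  nx <- nrow(image); ny <- ncol(image)
  bx <- pmin(grid, nx); by <- pmin(grid, ny)
  gx <- cut(seq_len(nx), bx, labels = FALSE)
  gy <- cut(seq_len(ny), by, labels = FALSE)
  df <- expand.grid(ix = seq_len(bx), iy = seq_len(by))
  df$q <- mapply(function(i, j) {
    stats::quantile(image[gx == i, gy == j], 0.1, names = FALSE)
  }, df$ix, df$iy)
  df$u <- (tapply(seq_len(nx), gx, mean))[df$ix] / nx * 2 - 1
  df$v <- (tapply(seq_len(ny), gy, mean))[df$iy] / ny * 2 - 1
  fit <- stats::lm(q ~ u + v + I(u^2) + I(u * v) + I(v^2), data = df)
  u <- seq_len(nx) / nx * 2 - 1
  v <- seq_len(ny) / ny * 2 - 1
  uv <- expand.grid(u = u, v = v)
  s <- matrix(stats::predict(fit, uv), nx, ny)
  pmax(s, 0.05 * stats::median(s))
}

#' Segment nuclei from a nuclear-marker image
#'
#' Global histogram threshold (inter-class variance maximization), hole
#' filling, marker-based watershed splitting of touching nuclei on the
#' distance transform, and removal of components below the minimum nuclear
#' area. Labels are re-assigned in raster order of the component centroids
#' (top-left first). A blank image yields an empty mask.
#'
#' @param nuclear_channel 2D intensity matrix.
#' @param cfg A [segmentation_config()].
#' @param cal Pixel calibration, um per pixel.
#' @param threshold Optional fixed intensity threshold overriding the
#'   histogram method.
#' @return Integer label matrix (0 = background).
#' @export
segment_nuclei <- function(nuclear_channel, cfg = segmentation_config(),
                           cal, threshold = NULL) {
  img <- nuclear_channel
  if (diff(range(img)) < .Machine$double.eps^0.5)
    return(matrix(0L, nrow(img), ncol(img)))
  if (is.null(threshold)) threshold <- otsu_threshold(as.vector(img))
  binary <- img > threshold
  if (!any(binary)) return(matrix(0L, nrow(img), ncol(img)))
  bin <- EBImage::fillHull(EBImage::Image(binary * 1))
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labm <- EBImage::imageData(lab)
  storage.mode(labm) <- "integer"
  # drop small components, relabel in raster order of centroids
  min_px <- cfg$min_nucleus_area_um2 / cal^2
  tab <- tabulate(labm)
  keep <- which(tab >= min_px)
  if (!length(keep)) return(matrix(0L, nrow(img), ncol(img)))
  cent <- component_centroids(labm, keep)
  ord <- keep[order(round(cent$y), cent$x)]
  relab <- integer(max(labm))
  relab[ord] <- seq_along(ord)
  out <- matrix(0L, nrow(img), ncol(img))
  nz <- labm > 0L
  out[nz] <- relab[labm[nz]]
  out
}

component_centroids <- function(labm, labels) {
  xs <- row(labm)[labm > 0]; ys <- col(labm)[labm > 0]
  ls <- labm[labm > 0]
  tibble::tibble(
    label = labels,
    x = tapply(xs, ls, mean)[as.character(labels)],
    y = tapply(ys, ls, mean)[as.character(labels)]
  )
}

# Otsu: inter-class variance maximization on a 256-bin histogram.
otsu_threshold <- function(values, n_bins = 256L) {
  r <- range(values)
  if (diff(r) == 0) stop("cannot threshold a constant sample", call. = FALSE)
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- hist(values, breaks = br, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

# Per-label Euclidean distance maps (distance of every pixel to nucleus k,
# 0 inside). Returns a [npix x nlab] matrix.
label_distance_stack <- function(mask) {
  labels <- sort(unique(mask[mask > 0]))
  d <- matrix(0, length(mask), length(labels))
  for (i in seq_along(labels)) {
    inv <- EBImage::Image((mask != labels[i]) * 1)
    d[, i] <- as.vector(EBImage::imageData(EBImage::distmap(inv)))
  }
  list(d = d, labels = labels)
}

#' Cytoplasmic ring regions
#'
#' The ring of cell k is the set of pixels whose Euclidean distance to
#' nucleus k lies within the 2-10 um band, that lie inside no nucleus, that
#' are farther than the exclusion distance (10 um) from every other
#' nucleus, and (when an intensity image is supplied) whose intensity is
#' distinguishable from background (above `median + 2 * mad` of the
#' background pixels, or above `cfg$background_floor` if set).
#'
#' @param mask Integer nuclear label matrix.
#' @param cfg A [segmentation_config()].
#' @param cal Pixel calibration, um per pixel.
#' @param intensity Optional reporter-channel image for the background rule.
#' @return Region tibble (`cell_id`, `region = "ring"`, `x`, `y`) with the
#'   calibration attached as attribute `"cal"`.
#' @export
cytoplasmic_ring <- function(mask, cfg = segmentation_config(), cal,
                             intensity = NULL) {
  ds <- label_distance_stack(mask)
  if (!length(ds$labels)) return(empty_region_tbl(cal))
  rin <- cfg$ring_inner_um / cal
  rout <- cfg$ring_outer_um / cal
  excl <- cfg$neighbor_exclusion_um / cal
  in_nuc <- as.vector(mask) > 0

  ok_int <- TRUE
  if (!is.null(intensity)) {
    v <- as.vector(intensity)
    near_any <- matrixStats_rowMins(ds$d) <= excl
    bg_px <- v[!near_any & !in_nuc]
    floor_v <- cfg$background_floor
    if (is.null(floor_v))
      floor_v <- stats::median(bg_px) + 2 * stats::mad(bg_px)
    ok_int <- v >= floor_v
  }

  out <- purrr::map_dfr(seq_along(ds$labels), function(i) {
    dk <- ds$d[, i]
    others <- ds$d[, -i, drop = FALSE]
    near_other <- if (ncol(others)) matrixStats_rowMins(others) <= excl
                  else FALSE
    sel <- dk >= rin & dk <= rout & !in_nuc & !near_other & ok_int
    pix_tbl(sel, nrow(mask), ds$labels[i], "ring")
  })
  attr(out, "cal") <- cal
  out
}

#' Whole-cell regions
#'
#' The whole-cell region of cell k is its nucleus plus every pixel within
#' the 50 um reach whose nearest nucleus is nucleus k (ties broken toward
#' the lower label), so regions never overlap.
#'
#' @inheritParams cytoplasmic_ring
#' @return Region tibble (`cell_id`, `region = "wholecell"`, `x`, `y`).
#' @export
whole_cell_regions <- function(mask, cfg = segmentation_config(), cal) {
  ds <- label_distance_stack(mask)
  if (!length(ds$labels)) return(empty_region_tbl(cal))
  reach <- cfg$wholecell_reach_um / cal
  nearest <- max.col(-ds$d, ties.method = "first")
  dmin <- ds$d[cbind(seq_len(nrow(ds$d)), nearest)]
  maskv <- as.vector(mask)
  out <- purrr::map_dfr(seq_along(ds$labels), function(i) {
    sel <- (nearest == i & dmin <= reach) | maskv == ds$labels[i]
    pix_tbl(sel, nrow(mask), ds$labels[i], "wholecell")
  })
  attr(out, "cal") <- cal
  out
}

#' Build all measurement regions from a nuclear mask
#'
#' Convenience wrapper returning nucleus, cytoplasmic-ring and (optionally)
#' whole-cell regions in one tibble sharing one set of distance transforms.
#'
#' @inheritParams cytoplasmic_ring
#' @param wholecell Whether to include whole-cell regions (they are only
#'   needed for FISH measurements and are the most expensive to build).
#' @return Region tibble with `region` in
#'   `c("nucleus", "ring", "wholecell")`.
#' @export
segment_regions <- function(mask, cfg = segmentation_config(), cal,
                            intensity = NULL, wholecell = FALSE) {
  labels <- sort(unique(mask[mask > 0]))
  nuc <- purrr::map_dfr(labels, function(k) {
    pix_tbl(as.vector(mask) == k, nrow(mask), k, "nucleus")
  })
  out <- dplyr::bind_rows(
    nuc,
    cytoplasmic_ring(mask, cfg, cal, intensity),
    if (wholecell) whole_cell_regions(mask, cfg, cal)
  )
  attr(out, "cal") <- cal
  out
}

#' Areas and centroids of a region set
#'
#' @param regions Region tibble.
#' @return Tibble with `cell_id`, `region`, `area_px`, `centroid_x`,
#'   `centroid_y` (pixel units).
#' @export
region_summary <- function(regions) {
  tibble::as_tibble(regions) |>
    dplyr::group_by(.data$cell_id, .data$region) |>
    dplyr::summarise(area_px = dplyr::n(),
                     centroid_x = mean(.data$x),
                     centroid_y = mean(.data$y), .groups = "drop")
}

pix_tbl <- function(sel, nx, cell_id, region) {
  ii <- which(sel)
  tibble::tibble(cell_id = as.integer(cell_id), region = region,
                 x = as.integer((ii - 1L) %% nx + 1L),
                 y = as.integer((ii - 1L) %/% nx + 1L))
}

empty_region_tbl <- function(cal) {
  out <- tibble::tibble(cell_id = integer(), region = character(),
                        x = integer(), y = integer())
  attr(out, "cal") <- cal
  out
}

# rowMins without matrixStats
matrixStats_rowMins <- function(m) {
  if (ncol(m) == 1) return(m[, 1])
  do.call(pmin, as.data.frame(m))
}
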
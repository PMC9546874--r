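#' Virtual microscopy parameters
#'
#' Geometry, illumination and noise of the rendered images. Cells are drawn
#' as a nuclear disk surrounded by a cytoplasmic annulus; KTR channels split
#' a fixed per-cell reporter amount between nucleus and cytoplasm so that
#' the cytoplasm-mean / nucleus-mean ratio equals the activity being
#' rendered.
#'
#' @param pixel_size_um Pixel pitch, um per pixel (default 0.65, a typical
#'   20x objective with 2x2 binning).
#' @param nucleus_radius_um,cyto_radius_um Nuclear and outer cytoplasmic
#'   radii, um (measured from the cell centre).
#' @param field_px Length-2 field size in pixels, `c(nx, ny)`.
#' @param bias_coeffs Optional length-5 quadratic illumination coefficients
#'   `c(cu, cv, cuu, cuv, cvv)` on centred unit coordinates; the
#'   multiplicative surface is `1 + cu*u + cv*v + cuu*u^2 + cuv*u*v +
#'   cvv*v^2`. `NULL` renders flat illumination.
#' @param background Background intensity offset, a.u.
#' @param ktr_amount Total reporter amount per cell and KTR channel, a.u.
#' @param nuc_amp Nuclear-marker amplitude, a.u.
#' @param degron_scale Nuclear degron intensity per degron unit, a.u.
#' @param shot_noise Apply Poisson shot noise.
#' @param read_noise Gaussian read-noise s.d., a.u. (0 disables).
#' @param jitter_sd_um Per-frame Brownian centre jitter s.d., um.
#' @param seed Seed for placement and noise.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(pixel_size_um = 0.65,
                           nucleus_radius_um = 5,
                           cyto_radius_um = 16,
                           field_px = c(256, 256),
                           bias_coeffs = NULL,
                           background = 100,
                           ktr_amount = 2e5,
                           nuc_amp = 800,
                           degron_scale = 300,
                           shot_noise = TRUE,
                           read_noise = 3,
                           jitter_sd_um = 0.2,
                           seed = 1) {
  stopifnot(pixel_size_um > 0, nucleus_radius_um > 0,
            nucleus_radius_um < cyto_radius_um, length(field_px) == 2)
  structure(list(pixel_size_um = pixel_size_um,
                 nucleus_radius_um = nucleus_radius_um,
                 cyto_radius_um = cyto_radius_um,
                 field_px = as.integer(field_px),
                 bias_coeffs = bias_coeffs, background = background,
                 ktr_amount = ktr_amount, nuc_amp = nuc_amp,
                 degron_scale = degron_scale, shot_noise = shot_noise,
                 read_noise = read_noise, jitter_sd_um = jitter_sd_um,
                 seed = as.integer(seed)),
            class = "imaging_params")
}

bias_surface <- function(imaging) {
  nx <- imaging$field_px[1]; ny <- imaging$field_px[2]
  if (is.null(imaging$bias_coeffs)) return(matrix(1, nx, ny))
  cf <- imaging$bias_coeffs
  u <- matrix(seq_len(nx) / nx * 2 - 1, nx, ny)
  v <- matrix(rep(seq_len(ny) / ny * 2 - 1, each = nx), nx, ny)
  s <- 1 + cf[1] * u + cf[2] * v + cf[3] * u^2 + cf[4] * u * v + cf[5] * v^2
  if (any(s <= 0)) stop("bias_coeffs give a non-positive surface",
                        call. = FALSE)
  s
}

# grid placement of n cells with margin; error if field too small
place_cells <- function(n, imaging) {
  nx <- imaging$field_px[1]; ny <- imaging$field_px[2]
  pitch <- 2 * imaging$cyto_radius_um / imaging$pixel_size_um + 6
  ncol_ <- max(1, floor((nx - pitch / 2) / pitch))
  nrow_ <- max(1, floor((ny - pitch / 2) / pitch))
  if (ncol_ * nrow_ < n)
    stop("field too small to place ", n, " cells without overlap",
         call. = FALSE)
  ix <- (seq_len(n) - 1) %% ncol_
  iy <- (seq_len(n) - 1) %/% ncol_
  tibble::tibble(
    cell_id = seq_len(n),
    x = pitch * (ix + 0.5) + (nx - ncol_ * pitch) / 2,
    y = pitch * (iy + 0.5) + (ny - nrow_ * pitch) / 2
  )
}

disk_idx <- function(cx, cy, r_px, nx, ny) {
  x0 <- max(1L, floor(cx - r_px)); x1 <- min(nx, ceiling(cx + r_px))
  y0 <- max(1L, floor(cy - r_px)); y1 <- min(ny, ceiling(cy + r_px))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r_px^2
  (g$y[keep] - 1L) * nx + g$x[keep]
}

#' Render a trace set into a virtual multichannel movie
#'
#' Draws each cell as a nuclear disk plus cytoplasmic annulus on every
#' frame. The nuclear-marker channel gets a constant-amplitude disk; each
#' KTR channel splits `ktr_amount` between nucleus and annulus so that
#' (cytoplasm mean) / (nucleus mean) equals the observed reporter activity
#' of that frame; the degron channel is a nuclear disk proportional to the
#' observed degron level. A multiplicative illumination surface is applied,
#' then Poisson shot noise and Gaussian read noise. Ground-truth nuclear
#' label masks (label = cell_id) and cell centres are returned per frame.
#'
#' @param traces A `trace_set` from [simulate_population()] (or any tibble
#'   with `cell_id`, `frame`, `r46_obs`, `r2_obs`, `degron_obs`).
#' @param imaging An [imaging_params()].
#' @return A list of class `rendered_movie`: `frames` (per frame, named
#'   list of channel matrices `nuclear`, `cdk4`, `cdk2`, `degron`), `masks`
#'   (per frame, integer label matrix), `positions` (tibble `cell_id`,
#'   `frame`, `x`, `y`), and the `imaging` parameters.
#' @export
render_movie <- function(traces, imaging = imaging_params()) {
  df <- tibble::as_tibble(traces)
  stopifnot(all(c("cell_id", "frame", "r46_obs", "r2_obs") %in% names(df)))
  if (!"degron_obs" %in% names(df)) df$degron_obs <- 0
  cells <- sort(unique(df$cell_id))
  frames <- sort(unique(df$frame))
  nx <- imaging$field_px[1]; ny <- imaging$field_px[2]
  px <- imaging$pixel_size_um
  rn_px <- imaging$nucleus_radius_um / px
  rc_px <- imaging$cyto_radius_um / px

  set.seed(imaging$seed)
  base <- place_cells(length(cells), imaging)
  jit_sd <- imaging$jitter_sd_um / px
  jx <- matrix(stats::rnorm(length(cells) * length(frames), 0, jit_sd),
               length(cells), length(frames))
  jy <- matrix(stats::rnorm(length(cells) * length(frames), 0, jit_sd),
               length(cells), length(frames))
  bias <- bias_surface(imaging)

  frames_out <- vector("list", length(frames))
  masks_out <- vector("list", length(frames))
  pos_list <- vector("list", length(frames))

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    sub <- df[df$frame == f, ]
    sub <- sub[match(cells, sub$cell_id), ]
    cx <- base$x + apply(jx[, seq_len(fi), drop = FALSE], 1, sum)
    cy <- base$y + apply(jy[, seq_len(fi), drop = FALSE], 1, sum)
    ch <- list(nuclear = matrix(0, nx, ny), cdk4 = matrix(0, nx, ny),
               cdk2 = matrix(0, nx, ny), degron = matrix(0, nx, ny))
    mask <- matrix(0L, nx, ny)
    for (ci in seq_along(cells)) {
      nuc <- disk_idx(cx[ci], cy[ci], rn_px, nx, ny)
      cyt <- setdiff(disk_idx(cx[ci], cy[ci], rc_px, nx, ny), nuc)
      mask[nuc] <- cells[ci]
      ch$nuclear[nuc] <- ch$nuclear[nuc] + imaging$nuc_amp
      for (kc in c("cdk4", "cdk2")) {
        act <- max(if (kc == "cdk4") sub$r46_obs[ci] else sub$r2_obs[ci], 0,
                   na.rm = TRUE)
        nmean <- imaging$ktr_amount / (length(nuc) + act * length(cyt))
        ch[[kc]][nuc] <- ch[[kc]][nuc] + nmean
        ch[[kc]][cyt] <- ch[[kc]][cyt] + act * nmean
      }
      dg <- max(sub$degron_obs[ci], 0, na.rm = TRUE)
      ch$degron[nuc] <- ch$degron[nuc] + dg * imaging$degron_scale
    }
    for (nm in names(ch)) {
      img <- (ch[[nm]] + imaging$background) * bias
      if (imaging$shot_noise)
        img <- matrix(stats::rpois(length(img), img), nx, ny)
      if (imaging$read_noise > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, imaging$read_noise),
                            nx, ny)
      ch[[nm]] <- img
    }
    frames_out[[fi]] <- ch
    masks_out[[fi]] <- mask
    pos_list[[fi]] <- tibble::tibble(cell_id = cells, frame = f,
                                     x = cx, y = cy)
  }
  structure(list(frames = frames_out, masks = masks_out,
                 positions = dplyr::bind_rows(pos_list), imaging = imaging),
            class = "rendered_movie")
}

#' Render an RNA FISH field with known puncta positions
#'
#' Places each transcript of each cell uniformly inside that cell's
#' whole-cell region and renders it as an isotropic Gaussian spot of fixed
#' peak amplitude over a constant background with read noise.
#'
#' @param counts Tibble with `cell_id` and `mrna_true` (transcripts per
#'   cell), e.g. from [cell_truth()].
#' @param regions Region tibble containing `wholecell` regions.
#' @param imaging An [imaging_params()].
#' @param spot_sigma_px Gaussian spot s.d., pixels.
#' @param spot_amp Peak spot amplitude, a.u.
#' @return A list: `image` (matrix), `centers` (tibble `cell_id`, `x`,
#'   `y`).
#' @export
render_fish_field <- function(counts, regions, imaging = imaging_params(),
                              spot_sigma_px = 2, spot_amp = 400) {
  cn <- tibble::as_tibble(counts)
  stopifnot(all(c("cell_id", "mrna_true") %in% names(cn)),
            all(cn$mrna_true >= 0))
  wc <- tibble::as_tibble(regions)
  wc <- wc[wc$region == "wholecell", ]
  nx <- imaging$field_px[1]; ny <- imaging$field_px[2]
  set.seed(imaging$seed)
  centers <- purrr::map_dfr(seq_len(nrow(cn)), function(i) {
    pix <- wc[wc$cell_id == cn$cell_id[i], ]
    k <- cn$mrna_true[i]
    if (k == 0 || nrow(pix) == 0) return(NULL)
    j <- sample.int(nrow(pix), k, replace = TRUE)
    tibble::tibble(cell_id = cn$cell_id[i],
                   x = pix$x[j] + stats::runif(k, -0.5, 0.5),
                   y = pix$y[j] + stats::runif(k, -0.5, 0.5))
  })
  img <- matrix(imaging$background, nx, ny)
  if (nrow(centers)) {
    half <- ceiling(4 * spot_sigma_px)
    for (i in seq_len(nrow(centers))) {
      x0 <- max(1L, floor(centers$x[i] - half))
      x1 <- min(nx, ceiling(centers$x[i] + half))
      y0 <- max(1L, floor(centers$y[i] - half))
      y1 <- min(ny, ceiling(centers$y[i] + half))
      xs <- x0:x1; ys <- y0:y1
      g <- outer((xs - centers$x[i])^2, (ys - centers$y[i])^2, "+")
      img[xs, ys] <- img[xs, ys] + spot_amp * exp(-g / (2 * spot_sigma_px^2))
    }
  }
  if (imaging$read_noise > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, imaging$read_noise),
                        nx, ny)
  list(image = img, centers = centers)
}
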
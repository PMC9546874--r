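#' Measure reporter intensities over segmentation regions
#'
#' For each cell and channel, computes the mean intensity over the nuclear
#' region and the cytoplasmic ring, background-subtracted. The background is
#' the median intensity over pixels belonging to no whole-cell region (or to
#' no region at all when whole-cell regions are absent); subtracted means
#' are floored at 0. Cells whose ring was entirely excluded are kept and
#' flagged, with `ring_mean` missing.
#'
#' @param images Named list of 2D intensity matrices (one per channel), all
#'   of identical dimension.
#' @param regions A region tibble from [segment_regions()] /
#'   [cytoplasmic_ring()] / [whole_cell_regions()] (columns `cell_id`,
#'   `region`, `x`, `y`).
#' @return A tibble with one row per cell x channel: `nuc_mean`,
#'   `ring_mean`, `bg`, `flag_no_ring`.
#' @export
measure_regions <- function(images, regions) {
  stopifnot(is.list(images), length(images) >= 1, !is.null(names(images)))
  dims <- dim(images[[1]])
  reg <- tibble::as_tibble(regions)
  stopifnot(all(c("cell_id", "region", "x", "y") %in% names(reg)))
  idx <- (reg$y - 1L) * dims[1] + reg$x

  bg_regions <- if ("wholecell" %in% reg$region) "wholecell" else
    unique(reg$region)
  occupied <- unique(idx[reg$region %in% bg_regions])
  bg_idx <- setdiff(seq_len(prod(dims)), occupied)

  cells <- sort(unique(reg$cell_id))
  purrr::map_dfr(names(images), function(ch) {
    img <- images[[ch]]
    stopifnot(all(dim(img) == dims))
    v <- as.vector(img)
    bg <- stats::median(v[bg_idx])
    nuc <- reg$region == "nucleus"
    ring <- reg$region == "ring"
    nm <- tapply(v[idx[nuc]], reg$cell_id[nuc], mean)
    rm_ <- tapply(v[idx[ring]], reg$cell_id[ring], mean)
    tibble::tibble(
      cell_id = cells,
      channel = ch,
      nuc_mean = pmax(unname(nm[as.character(cells)]) - bg, 0),
      ring_mean = pmax(unname(rm_[as.character(cells)]) - bg, 0),
      bg = bg,
      flag_no_ring = !(cells %in% reg$cell_id[ring])
    )
  })
}

#' Kinase translocation reporter activity
#'
#' The KTR readout: cytoplasmic (ring) mean over nuclear mean. Active kinase
#' drives the reporter into the cytoplasm, so higher ratios mean higher
#' activity.
#'
#' @param nuc_mean,ring_mean Background-subtracted region means
#'   (vectorized). `ring_mean` may be `NA` for flagged cells.
#' @return Dimensionless activity, `NA` where `ring_mean` is missing.
#' @export
ktr_activity <- function(nuc_mean, ring_mean) {
  if (any(!is.na(nuc_mean) & nuc_mean <= 0))
    stop("undefined activity: nuc_mean must be > 0", call. = FALSE)
  ring_mean / nuc_mean
}

#' Estimate reporter cross-talk by calibration regression
#'
#' Ordinary least squares of the CDK4/6-reporter signal on the CDK2-reporter
#' signal measured under full CDK4/6 inhibition, where any CDK4/6-reporter
#' signal is CDK2 leak-through. The slope is the cross-talk coefficient used
#' by [correct_cdk46()]; the intercept is reported but not used by the
#' correction.
#'
#' @param pairs Data frame with columns `r46_obs` and `r2_obs` (e.g. from
#'   [simulate_calibration_pairs()]).
#' @return An object of class `crosstalk_model`: `rho`, `intercept`,
#'   `n_points`, `residual_sd`, and the underlying `lm` fit.
#' @export
estimate_crosstalk <- function(pairs) {
  df <- tibble::as_tibble(pairs)
  stopifnot(all(c("r46_obs", "r2_obs") %in% names(df)))
  if (nrow(df) < 2 || length(unique(df$r2_obs)) < 2)
    stop("singular calibration: need >= 2 distinct CDK2 reporter values",
         call. = FALSE)
  fit <- stats::lm(r46_obs ~ r2_obs, data = df)
  out <- list(rho = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              n_points = nrow(df),
              residual_sd = stats::sigma(fit),
              fit = fit)
  class(out) <- "crosstalk_model"
  out
}

#' @export
print.crosstalk_model <- function(x, ...) {
  cat(sprintf(
    "<crosstalk_model> rho = %.4f (intercept %.4f, residual sd %.4f, n = %d)\n",
    x$rho, x$intercept, x$residual_sd, x$n_points))
  invisible(x)
}

#' Correct CDK4/6 reporter activity for CDK2 cross-talk
#'
#' Subtracts the proportional CDK2 leak-through:
#' `corrected = r46 - rho * r2`. No clipping is applied; corrected values
#' may be negative. The regression intercept is deliberately not
#' subtracted.
#'
#' @param r46,r2 Raw CDK4/6 and CDK2 reporter activities (vectorized).
#' @param model A `crosstalk_model` from [estimate_crosstalk()], or a bare
#'   numeric cross-talk coefficient.
#' @return Corrected CDK4/6 activity.
#' @export
correct_cdk46 <- function(r46, r2, model) {
  rho <- if (inherits(model, "crosstalk_model")) model$rho else
    as.numeric(model)
  stopifnot(is.finite(rho))
  r46 - rho * r2
}

#' Nuclear degron level per cell
#'
#' Background-subtracted mean nuclear intensity of the APC/C degron channel
#' (the degron accumulates once APC/C-Cdh1 is inactivated near S-phase
#' onset).
#'
#' @param image 2D intensity matrix of the degron channel.
#' @param regions Region tibble containing nucleus regions.
#' @return Tibble with `cell_id` and `degron` (floored at 0).
#' @export
degron_level <- function(image, regions) {
  m <- measure_regions(list(degron = image), regions)
  tibble::tibble(cell_id = m$cell_id, degron = m$nuc_mean)
}

#' Count FISH puncta per cell by top-hat filtering
#'
#' White top-hat filters the FISH image with a disk structuring element of
#' radius `fish_kernel_radius_um` (removing all structure larger than the
#' kernel, including any constant background), thresholds the result at an
#' absolute intensity, and reports per cell (a) the number of above-threshold
#' pixels inside the whole-cell region (the puncta-pixel parameter) and
#' (b) the number of connected components.
#'
#' @param fish_image 2D intensity matrix.
#' @param regions Region tibble containing `wholecell` regions.
#' @param cfg A [segmentation_config()] (for the kernel radius).
#' @param cal Pixel calibration, um per pixel.
#' @param threshold Absolute intensity threshold on the top-hat image;
#'   default `median + 5 * mad` of the top-hat image.
#' @return Tibble with `cell_id`, `puncta_pixels`, `puncta_count`,
#'   `threshold`.
#' @export
fish_puncta_per_cell <- function(fish_image, regions,
                                 cfg = segmentation_config(), cal,
                                 threshold = NULL) {
  r_px <- max(1L, round(cfg$fish_kernel_radius_um / cal))
  if (2 * r_px + 1 > min(dim(fish_image)))
    stop("top-hat kernel larger than the image", call. = FALSE)
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  # EBImage grayscale morphology clamps to [0, 1]; the top-hat commutes with
  # affine rescaling, so normalize, filter, and scale back (exact).
  sc <- max(fish_image, 1e-12)
  th_img <- EBImage::whiteTopHat(EBImage::Image(fish_image / sc), brush)
  th <- EBImage::imageData(th_img) * sc
  if (is.null(threshold))
    threshold <- stats::median(th) + 5 * stats::mad(th)
  mask <- th > threshold
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))

  reg <- tibble::as_tibble(regions)
  wc <- reg[reg$region == "wholecell", ]
  if (nrow(wc) == 0) stop("regions contain no wholecell entries",
                          call. = FALSE)
  idx <- (wc$y - 1L) * dim(fish_image)[1] + wc$x
  labs <- as.vector(lab)[idx]
  wc |>
    dplyr::mutate(lab = labs) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      puncta_pixels = sum(.data$lab > 0),
      puncta_count = length(unique(.data$lab[.data$lab > 0])),
      .groups = "drop"
    ) |>
    dplyr::mutate(threshold = threshold)
}
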
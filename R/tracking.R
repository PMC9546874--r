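#' Tracking configuration
#'
#' @param max_step_um Per-frame displacement gate, um.
#' @param max_gap Maximum number of missing frames a bridge may span.
#' @param mass_tolerance Maximum relative nuclear-mass change across a
#'   bridge.
#' @param fixed_map_radius_um Gate for mapping the final live frame to the
#'   fixed-cell image, um.
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(max_step_um = 15, max_gap = 2,
                            mass_tolerance = 0.3, fixed_map_radius_um = 15) {
  stopifnot(max_step_um > 0, max_gap >= 0, mass_tolerance > 0,
            fixed_map_radius_um > 0)
  structure(list(max_step_um = max_step_um, max_gap = as.integer(max_gap),
                 mass_tolerance = mass_tolerance,
                 fixed_map_radius_um = fixed_map_radius_um),
            class = "tracking_config")
}

#' Extract detections from a label mask
#'
#' @param mask Integer label matrix.
#' @param image Optional intensity image for the nuclear mass (total
#'   intensity over the label); mass is the pixel count otherwise.
#' @param frame Frame number to record.
#' @return Tibble `frame`, `label`, `x`, `y` (pixel centroids), `mass`.
#' @export
detections_from_mask <- function(mask, image = NULL, frame = 1L) {
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs)) {
    return(tibble::tibble(frame = integer(), label = integer(),
                          x = numeric(), y = numeric(), mass = numeric()))
  }
  xs <- row(mask)[mask > 0]; ys <- col(mask)[mask > 0]
  ls <- mask[mask > 0]
  w <- if (is.null(image)) rep(1, length(ls)) else image[mask > 0]
  key <- as.character(labs)
  tibble::tibble(
    frame = as.integer(frame), label = as.integer(labs),
    x = unname(tapply(xs * w, ls, sum)[key] / tapply(w, ls, sum)[key]),
    y = unname(tapply(ys * w, ls, sum)[key] / tapply(w, ls, sum)[key]),
    mass = unname(tapply(w, ls, sum)[key])
  )
}

# Jonker-Volgenant style shortest-augmenting-path solver for the square
# linear assignment problem (minimization). Returns, for each row, the
# assigned column. Deterministic.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n == m)
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1)        # row potentials, u[i + 1]
  v <- numeric(m + 1)        # column potentials, v[j + 1]
  p <- integer(m + 1)        # p[j + 1] = row assigned to column j (0 none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_of_row <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assign_of_row[p[j + 1]] <- j
  assign_of_row
}

# Gated partial matching: minimizes total cost over matches with
# cost <= gate, where leaving a detection unmatched costs `gate`. Returns
# for each row the matched column index or NA.
gated_match <- function(cost, gate) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  BIG <- (max(gate, cost[is.finite(cost)], 0) + 1) * (n + m + 1)
  size <- n + m
  C <- matrix(BIG, size, size)
  C[seq_len(n), seq_len(m)] <- ifelse(cost <= gate, cost, BIG)
  for (i in seq_len(n)) C[i, m + i] <- gate
  for (j in seq_len(m)) C[n + j, j] <- gate
  C[(n + 1):size, (m + 1):size] <- 0
  a <- solve_assignment(C)
  out <- a[seq_len(n)]
  out[out > m] <- NA_integer_
  # a gated pair forced at BIG counts as unmatched
  mi <- which(!is.na(out))
  if (length(mi)) {
    bad <- cost[cbind(mi, out[mi])] > gate
    out[mi[bad]] <- NA_integer_
  }
  out
}

#' Link detections between two consecutive frames
#'
#' One-to-one assignment minimizing total squared displacement among pairs
#' within the displacement gate; detections left unmatched become track
#' ends (frame t) or starts (frame t+1). The result is invariant to the
#' input order of detections (they are canonically sorted internally).
#'
#' @param dets_t,dets_t1 Detection tibbles (columns `x`, `y`, optionally
#'   `mass`) for frames t and t+1.
#' @param cfg A [tracking_config()].
#' @param cal Pixel calibration, um per pixel (gates are in um).
#' @return Tibble with one row per detection of frame t: `from` (row in
#'   `dets_t`), `to` (row in `dets_t1` or `NA`), `cost` (squared
#'   displacement, um^2).
#' @export
link_frames <- function(dets_t, dets_t1, cfg = tracking_config(), cal = 1) {
  a <- tibble::as_tibble(dets_t); b <- tibble::as_tibble(dets_t1)
  n <- nrow(a); m <- nrow(b)
  if (n == 0) return(tibble::tibble(from = integer(), to = integer(),
                                    cost = numeric()))
  oa <- order(a$x, a$y); ob <- order(b$x, b$y)
  gate2 <- (cfg$max_step_um)^2
  if (m == 0) {
    return(tibble::tibble(from = seq_len(n), to = NA_integer_,
                          cost = NA_real_))
  }
  dx <- outer(a$x[oa], b$x[ob], "-") * cal
  dy <- outer(a$y[oa], b$y[ob], "-") * cal
  cost <- dx^2 + dy^2
  mt <- gated_match(cost, gate2)
  to <- rep(NA_integer_, n)
  to[oa] <- ob[mt]
  tibble::tibble(
    from = seq_len(n), to = to,
    cost = ifelse(is.na(to), NA_real_,
                  ((a$x - b$x[to]) * cal)^2 + ((a$y - b$y[to]) * cal)^2)
  )
}

#' Build single-cell tracks across a movie
#'
#' Frame-by-frame optimal linking ([link_frames()]), followed by gap
#' bridging: a track ending at frame t is joined to a track starting at
#' frame t+g+1 (g <= `max_gap` missing frames) when the displacement is
#' within `(g+1) * max_step_um` and the relative nuclear-mass change is
#' within `mass_tolerance`. All bridge candidates are resolved jointly by
#' optimal assignment (so a bridge can displace a worse competing bridge),
#' and bridging is iterated to a fixed point. A track whose mass halves
#' between consecutive observations is flagged, never split.
#'
#' @param dets Detection tibble for all frames (columns `frame`, `x`, `y`,
#'   optionally `mass`, `label`).
#' @param cfg A [tracking_config()].
#' @param cal Pixel calibration, um per pixel.
#' @return Tibble `track_id`, `frame`, `x`, `y`, `mass`, `label`,
#'   `bridged` (TRUE on the first detection after a bridged gap),
#'   `mass_warning` (per-track flag).
#' @export
build_tracks <- function(dets, cfg = tracking_config(), cal = 1) {
  d <- tibble::as_tibble(dets)
  stopifnot(all(c("frame", "x", "y") %in% names(d)))
  if (!"mass" %in% names(d)) d$mass <- NA_real_
  if (!"label" %in% names(d)) d$label <- NA_integer_
  d <- d[order(d$frame, d$x, d$y), ]
  d$det_id <- seq_len(nrow(d))
  frames <- sort(unique(d$frame))

  track_of <- integer(nrow(d))
  next_track <- 0L
  prev_rows <- integer(0)
  prev_f <- NA_integer_
  for (f in frames) {
    rows <- which(d$frame == f)
    # only consecutive frames are linked directly; larger jumps are left to
    # the mass-gated bridging stage
    if (!length(prev_rows) || is.na(prev_f) || f - prev_f != 1L) {
      track_of[rows] <- next_track + seq_along(rows)
      next_track <- next_track + length(rows)
    } else {
      lk <- link_frames(d[prev_rows, ], d[rows, ], cfg, cal)
      matched <- !is.na(lk$to)
      track_of[rows[lk$to[matched]]] <- track_of[prev_rows[lk$from[matched]]]
      new_rows <- rows[!(seq_along(rows) %in% lk$to[matched])]
      if (length(new_rows)) {
        track_of[new_rows] <- next_track + seq_along(new_rows)
        next_track <- next_track + length(new_rows)
      }
    }
    prev_rows <- rows
    prev_f <- f
  }
  d$track_id <- track_of
  d$bridged <- FALSE

  # iterative assignment-based gap bridging
  repeat {
    info <- d |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(
        f_start = min(.data$frame), f_end = max(.data$frame),
        x_start = .data$x[which.min(.data$frame)],
        y_start = .data$y[which.min(.data$frame)],
        x_end = .data$x[which.max(.data$frame)],
        y_end = .data$y[which.max(.data$frame)],
        m_start = .data$mass[which.min(.data$frame)],
        m_end = .data$mass[which.max(.data$frame)],
        .groups = "drop")
    ends <- info; starts <- info
    span <- outer(starts$f_start, ends$f_end, "-")   # [start, end]
    gap_ok <- span >= 2 & (span - 1) <= cfg$max_gap
    if (!any(gap_ok)) break
    dx <- outer(starts$x_start, ends$x_end, "-") * cal
    dy <- outer(starts$y_start, ends$y_end, "-") * cal
    disp2 <- dx^2 + dy^2
    gate2 <- (span * cfg$max_step_um)^2
    mass_ok <- outer(starts$m_start, ends$m_end,
                     function(ms, me) is.na(ms) | is.na(me) |
                       abs(ms - me) / pmax(me, .Machine$double.eps) <=
                       cfg$mass_tolerance)
    cost <- ifelse(gap_ok & disp2 <= gate2 & mass_ok, disp2, Inf)
    if (!any(is.finite(cost))) break
    gate <- max(cost[is.finite(cost)]) + 1
    cost[!is.finite(cost)] <- 2 * gate * (nrow(cost) + 1)
    mt <- gated_match(cost, gate)     # rows = starts, cols = ends
    merged <- FALSE
    for (i in which(!is.na(mt))) {
      st <- starts$track_id[i]; en <- ends$track_id[mt[i]]
      if (st == en) next
      first_row <- which(d$track_id == st & d$frame == starts$f_start[i])
      d$bridged[first_row] <- TRUE
      d$track_id[d$track_id == st] <- en
      merged <- TRUE
    }
    if (!merged) break
  }

  d <- d |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(mass_warning = any(
      !is.na(.data$mass) & dplyr::lag(.data$mass) > 0 &
        .data$mass < 0.5 * dplyr::lag(.data$mass), na.rm = TRUE)) |>
    dplyr::ungroup()

  # renumber tracks deterministically by first appearance
  first <- d |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(f = min(.data$frame),
                     x0 = .data$x[which.min(.data$frame)], .groups = "drop") |>
    dplyr::arrange(.data$f, .data$x0)
  remap <- stats::setNames(seq_len(nrow(first)), first$track_id)
  d$track_id <- unname(remap[as.character(d$track_id)])
  d[order(d$track_id, d$frame),
    c("track_id", "frame", "x", "y", "mass", "label", "bridged",
      "mass_warning")]
}

#' Map the final live-cell frame to a fixed-cell image
#'
#' Optimal assignment between live and fixed detections within the mapping
#' radius; fixed cells without a live partner are reported unmapped.
#'
#' @param live_dets Detections of the final live frame.
#' @param fixed_dets Detections of the fixed-cell image (same coordinate
#'   frame).
#' @param cfg A [tracking_config()].
#' @param cal Pixel calibration, um per pixel.
#' @return Tibble with one row per fixed detection: `fixed_id`, `live_id`
#'   (row in `live_dets` or `NA`), `distance_um`.
#' @export
map_fixed_to_live <- function(live_dets, fixed_dets,
                              cfg = tracking_config(), cal = 1) {
  lv <- tibble::as_tibble(live_dets); fx <- tibble::as_tibble(fixed_dets)
  cfg2 <- cfg
  cfg2$max_step_um <- cfg$fixed_map_radius_um
  lk <- link_frames(fx, lv, cfg2, cal)
  tibble::tibble(fixed_id = lk$from, live_id = lk$to,
                 distance_um = sqrt(lk$cost))
}
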
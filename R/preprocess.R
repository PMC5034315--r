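#' Global camera background from the bottom-right corner patch
#'
#' Mean brightness of the 64 x 64 pixel square at the bottom right of
#' the frame, an area that never contains tubes; the caller subtracts it
#' from every pixel. Estimated per frame so that slow temporal drift in
#' the camera baseline is tracked.
#'
#' @param frame Numeric matrix `[y, x]`.
#' @param patch Patch side length in pixels.
#' @return Scalar mean counts.
#' @export
estimate_global_background <- function(frame, patch = 64L) {
  H <- nrow(frame); W <- ncol(frame)
  if (H < patch || W < patch)
    stop(sprintf("frame (%d x %d) smaller than the %d x %d background patch",
                 W, H, patch, patch), call. = FALSE)
  mean(frame[(H - patch + 1L):H, (W - patch + 1L):W])
}

# rotate (x, y) points about the image centre; positive angle rotates
# toward increasing y for a point at positive x (y axis points down)
rotate_points <- function(points, deg, image_size) {
  th <- deg * pi / 180
  cx <- (image_size[1] + 1) / 2; cy <- (image_size[2] + 1) / 2
  dx <- points[, 1] - cx; dy <- points[, 2] - cy
  out <- cbind(x = cx + cos(th) * dx - sin(th) * dy,
               y = cy + sin(th) * dx + cos(th) * dy)
  out
}

#' Rotate a frame about its centre (bilinear interpolation)
#'
#' Pixels sampled from outside the source frame become 0. A rotation of
#' exactly 0 degrees is an identity.
#'
#' @param frame Numeric matrix `[y, x]`.
#' @param deg Rotation angle in degrees, same convention as the marker
#'   points: positive rotates the content clockwise on screen.
#' @return Numeric matrix of the same size.
#' @export
rotate_frame <- function(frame, deg) {
  if (deg == 0) return(frame)
  H <- nrow(frame); W <- ncol(frame)
  th <- deg * pi / 180
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  dx <- matrix(rep(seq_len(W) - cx, each = H), H, W)
  dy <- matrix(rep(seq_len(H) - cy, times = W), H, W)
  # inverse mapping: source coords for each target pixel
  u <- cx + cos(th) * dx + sin(th) * dy
  v <- cy - sin(th) * dx + cos(th) * dy
  x0 <- floor(u); y0 <- floor(v)
  fx <- u - x0; fy <- v - y0
  pix <- function(xx, yy) {
    ok <- xx >= 1 & xx <= W & yy >= 1 & yy <= H
    val <- numeric(length(xx))
    val[ok] <- frame[cbind(yy[ok], xx[ok])]
    val
  }
  out <- (1 - fx) * (1 - fy) * pix(x0, y0) +
    fx * (1 - fy) * pix(x0 + 1, y0) +
    (1 - fx) * fy * pix(x0, y0 + 1) +
    fx * fy * pix(x0 + 1, y0 + 1)
  matrix(out, H, W)
}

# sub-pixel marker centre: intensity-weighted centre of mass in a small
# window around the approximate location
refine_marker <- function(frame, x_approx, y_approx, window = 6L) {
  xs <- max(1L, round(x_approx) - window):min(ncol(frame), round(x_approx) + window)
  ys <- max(1L, round(y_approx) - window):min(nrow(frame), round(y_approx) + window)
  w <- frame[ys, xs, drop = FALSE]
  w <- w - min(w)
  if (sum(w) <= 0) return(c(x = x_approx, y = y_approx))
  c(x = sum(colSums(w) * xs) / sum(w), y = sum(rowSums(w) * ys) / sum(w))
}

#' Tray rotation implied by three corner markers
#'
#' The three markers sit at corners of the rectangular tray, so the two
#' shortest pairwise segments are tray edges; their (length-weighted)
#' mean deviation from the nearest image axis, taken modulo 90 degrees,
#' is the tray's rotation. Invariant to the order of the points.
#'
#' @param points 3 x 2 matrix of (x, y) marker positions.
#' @return Rotation of the tray in degrees (positive = clockwise).
#' @export
rotation_from_markers <- function(points) {
  stopifnot(nrow(points) == 3)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  seg <- t(vapply(pairs, function(p) points[p[2], ] - points[p[1], ], numeric(2)))
  len <- sqrt(rowSums(seg^2))
  if (any(len < 1e-6))
    stop("duplicate marker points", call. = FALSE)
  area2 <- abs(seg[1, 1] * seg[2, 2] - seg[1, 2] * seg[2, 1])
  if (area2 / max(len)^2 < 1e-3)
    stop("marker points are collinear", call. = FALSE)
  edges <- order(len)[1:2]
  dev <- vapply(edges, function(i) {
    ang <- atan2(seg[i, 2], seg[i, 1]) * 180 / pi
    ((ang + 45) %% 90) - 45
  }, numeric(1))
  sum(dev * len[edges]) / sum(len[edges])
}

#' Align the tray so tube long axes are parallel to the image y-axis
#'
#' Refines the supplied approximate marker positions to sub-pixel
#' centroids, derives the tray rotation from them, and rotates the frame
#' by the opposite angle about the image centre (bilinear). The returned
#' `rotation_deg` is the correction that was applied; the same transform
#' should be reused for every frame of a stack (see [align_stack()]).
#'
#' @param frame Numeric matrix `[y, x]`.
#' @param marker_points 3 x 2 matrix of approximate (x, y) marker
#'   positions (manual clicks, or the simulator's rendered truth).
#' @param refine Refine markers by local centre of mass first?
#' @return List with `frame` (aligned), `rotation_deg` (applied
#'   correction), `marker_points` (refined, in input-frame coordinates).
#' @export
align_tray <- function(frame, marker_points, refine = TRUE) {
  mp <- as.matrix(marker_points)
  if (refine)
    mp <- t(apply(mp, 1, function(p) refine_marker(frame, p[1], p[2])))
  correction <- -rotation_from_markers(mp)
  list(frame = rotate_frame(frame, correction),
       rotation_deg = correction, marker_points = mp)
}

#' Align every frame of a stack with one shared transform
#'
#' The rotation is estimated once, from the markers on the first frame,
#' and applied to all frames.
#'
#' @param stack A `frame_stack`.
#' @param marker_points Approximate marker positions (defaults to the
#'   marker positions stored with the stack).
#' @return The stack with aligned frames; `geometry$rotation_deg` records
#'   the applied correction.
#' @export
align_stack <- function(stack, marker_points = stack$geometry$marker_points) {
  stopifnot(inherits(stack, "frame_stack"))
  first <- align_tray(stack$frames[[1]], marker_points)
  stack$frames[[1]] <- first$frame
  if (length(stack$frames) > 1 && first$rotation_deg != 0)
    stack$frames[-1] <- lapply(stack$frames[-1], rotate_frame, deg = first$rotation_deg)
  stack$geometry$rotation_deg <- first$rotation_deg
  stack$geometry$marker_points <-
    rotate_points(first$marker_points, first$rotation_deg, stack$image_size)
  stack
}

#' Mean projection of the early recording, for tube detection
#'
#' Per-pixel mean of all frames in the first `hours` of the recording,
#' each with its global background subtracted. Averaging over a full
#' circadian day of frames washes out the fly positions so the tube
#' outlines dominate the projection.
#'
#' @param stack An aligned `frame_stack`.
#' @param hours Projection depth in hours.
#' @return Numeric matrix.
#' @export
reference_frame <- function(stack, hours = 24) {
  idx <- which(stack$t_h <= hours)
  if (!length(idx)) idx <- 1L
  acc <- 0
  for (f in idx)
    acc <- acc + (stack$frames[[f]] - estimate_global_background(stack$frames[[f]]))
  acc / length(idx)
}

# greedy peak picking on a smoothed 1-d profile with a minimum spacing
profile_peaks <- function(p, min_sep, min_height) {
  n <- length(p)
  cand <- which(p > c(-Inf, p[-n]) & p >= c(p[-1], -Inf) & p > min_height)
  cand <- cand[order(p[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (k in cand)
    if (!length(keep) || all(abs(keep - k) >= min_sep)) keep <- c(keep, k)
  sort(keep)
}

#' Detect tube rectangles from intensity projections
#'
#' On an aligned, globally background-subtracted reference frame, the
#' profile of pixel intensities summed along y oscillates with one peak
#' per tube column; the profile summed along x shows one plateau per
#' tube row. Each tube is assigned a boundary rectangle of the stated
#' width (17 px) centred on its column peak and spanning its row
#' plateau, plus a 5-px-wide background rectangle centred midway to the
#' neighbouring column.
#'
#' @param ref_frame Numeric matrix from [reference_frame()].
#' @param n_columns,n_rows Expected tube layout.
#' @param tube_width_px,tube_length_px,bg_width_px Geometry constants.
#' @return A `tray_geometry`.
#' @export
detect_tubes <- function(ref_frame, n_columns, n_rows,
                         tube_width_px = 17L, tube_length_px = 184L,
                         bg_width_px = 5L) {
  W <- ncol(ref_frame); H <- nrow(ref_frame)
  smooth5 <- function(x) as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2))
  fill_na <- function(x) { x[is.na(x)] <- min(x, na.rm = TRUE); x }

  px <- fill_na(smooth5(colSums(ref_frame)))
  base_x <- stats::median(px)
  if (max(px) - base_x <= 0)
    stop("tube detection failed: flat x-projection (blank frame?)", call. = FALSE)
  cols <- profile_peaks(px, min_sep = tube_width_px,
                        min_height = base_x + 0.25 * (max(px) - base_x))
  if (length(cols) > n_columns && n_columns >= 2) {
    # bright corner markers can add flanking peaks; keep the window of
    # n_columns peaks with the most uniform centre-to-centre pitch
    spread <- vapply(seq_len(length(cols) - n_columns + 1), function(i) {
      stats::var(diff(cols[i:(i + n_columns - 1)]))
    }, numeric(1))
    cols <- cols[which.min(spread) + seq_len(n_columns) - 1]
  }
  if (length(cols) != n_columns)
    stop(sprintf("tube detection found %d column peaks (expected %d) at x = %s",
                 length(cols), n_columns, paste(cols, collapse = ", ")),
         call. = FALSE)

  xr <- pmin(pmax(unlist(lapply(cols, function(c0)
    (c0 - (tube_width_px - 1) %/% 2):(c0 + tube_width_px %/% 2))), 1), W)
  xr <- unique(xr)
  # row-wise baseline from the inter-tube columns cancels the vignette
  mids <- round(c(cols[1] - mean(diff(cols)) / 2,
                  cols[-length(cols)] + diff(cols) / 2,
                  cols[length(cols)] + mean(diff(cols)) / 2))
  xb <- unique(pmin(pmax(unlist(lapply(mids, function(m0)
    (m0 - 2):(m0 + 2))), 1), W))
  xb <- setdiff(xb, xr)
  raw_py <- rowSums(ref_frame[, xr, drop = FALSE]) -
    rowSums(ref_frame[, xb, drop = FALSE]) * (length(xr) / length(xb))
  py <- fill_na(as.numeric(stats::filter(raw_py, rep(1 / 11, 11), sides = 2)))
  # rows outside the tubes define the baseline and its noise; the tube
  # glow plateau sits several sigma above it even where the fly never went
  low <- py[py <= stats::quantile(py, 0.25, names = FALSE)]
  base_y <- mean(low)
  sd_y <- max(stats::sd(low), 1e-12)
  if (max(py) - base_y <= 4 * sd_y || max(py) <= base_y)
    stop("tube detection failed: flat y-projection", call. = FALSE)
  above <- py > base_y + 4 * sd_y
  # hysteresis: grow detected rows outward at a lower threshold so
  # band edges do not erode when the glow sits close to the noise
  lo <- py > base_y + 2 * sd_y
  repeat {
    grown <- above | (lo & (c(FALSE, above[-H]) | c(above[-1], FALSE)))
    if (identical(grown, above)) break
    above <- grown
  }
  # bridge short within-tube gaps
  r0 <- rle(above)
  gap <- !r0$values & r0$lengths < 8
  gap[c(1, length(gap))] <- FALSE
  r0$values[gap] <- TRUE
  above <- inverse.rle(r0)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= tube_length_px / 2)
  if (length(runs) != n_rows)
    stop(sprintf("tube detection found %d row bands (expected %d)",
                 length(runs), n_rows), call. = FALSE)
  row_centre <- (starts[runs] + ends[runs]) / 2
  y_min <- round(row_centre - tube_length_px / 2 + 0.5)

  half_w <- (tube_width_px - 1L) %/% 2L
  grid <- expand.grid(column = seq_len(n_columns), row = seq_len(n_rows))
  cx <- cols[grid$column]
  bg_mid <- ifelse(grid$column < n_columns,
                   (cols[grid$column] + cols[pmin(grid$column + 1L, n_columns)]) / 2,
                   (cols[pmax(grid$column - 1L, 1L)] + cols[grid$column]) / 2)
  tubes <- tibble::tibble(
    tube_id = seq_len(nrow(grid)),
    column = grid$column, row = grid$row,
    x_min = as.integer(cx - half_w), x_max = as.integer(cx - half_w + tube_width_px - 1L),
    y_min = as.integer(y_min[grid$row]),
    y_max = as.integer(y_min[grid$row] + tube_length_px - 1L),
    bg_x_min = as.integer(round(bg_mid) - (bg_width_px - 1L) %/% 2L),
    bg_x_max = as.integer(round(bg_mid) + bg_width_px %/% 2L),
    bg_y_min = as.integer(y_min[grid$row]),
    bg_y_max = as.integer(y_min[grid$row] + tube_length_px - 1L)
  )
  structure(list(tubes = tubes, marker_points = NULL, rotation_deg = 0,
                 image_size = c(W, H), n_bins = as.integer(tube_length_px / 4L)),
            class = "tray_geometry")
}

#' Local (inter-tube) background for one tube
#'
#' Mean of the tube's 5-px-wide background rectangle, which corrects the
#' smooth vignette-driven variation in brightness across the sensor.
#' Subtracted from that tube's pixels only.
#'
#' @param frame Numeric matrix (globally background-subtracted).
#' @param geometry A `tray_geometry`.
#' @param tube_id Tube index.
#' @return Scalar counts.
#' @export
local_background <- function(frame, geometry, tube_id) {
  tb <- geometry$tubes[geometry$tubes$tube_id == tube_id, ]
  if (nrow(tb) != 1) stop("unknown tube_id: ", tube_id, call. = FALSE)
  if (tb$bg_x_min < 1 || tb$bg_y_min < 1 ||
      tb$bg_x_max > ncol(frame) || tb$bg_y_max > nrow(frame))
    stop("background rectangle lies outside the frame", call. = FALSE)
  mean(frame[tb$bg_y_min:tb$bg_y_max, tb$bg_x_min:tb$bg_x_max])
}

#' Serialise / load tray geometry as JSON
#'
#' @param geometry A `tray_geometry`.
#' @param path JSON file path.
#' @return `write_geometry()` the path invisibly; `read_geometry()` a
#'   `tray_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  jsonlite::write_json(geometry_to_list(geometry), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  list_to_geometry(jsonlite::read_json(path, simplifyVector = TRUE))
}
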
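#' True tray geometry implied by a simulation configuration
#'
#' Lays the configured tube grid out on the sensor, centred, and derives
#' the per-tube boundary rectangles (17 px wide by default), the paired
#' 5-px inter-tube background rectangles centred on the midpoint between
#' adjacent tube columns (the outermost column uses the midpoint toward
#' its single inner neighbour), and the three corner marker positions.
#' Pixel coordinates are 1-based closed intervals with y increasing
#' downward; the tube long axis is y.
#'
#' @param config A [sim_config()].
#' @return A `tray_geometry` object: list with `tubes` (tibble), 3x2
#'   `marker_points` matrix (x, y), `rotation_deg`, `image_size`,
#'   `n_bins`.
#' @export
sim_layout <- function(config) {
  W <- config$image_size[1]; H <- config$image_size[2]
  nc <- config$n_columns; nr <- config$n_rows
  pitch <- config$column_pitch_px
  len <- config$tube_length_px; wid <- config$tube_width_px
  half_w <- (wid - 1L) %/% 2L

  left <- round((W - nc * pitch) / 2)
  top <- round((H - nr * (len + config$row_gap_px)) / 2)
  col_centre <- round(left + (seq_len(nc) - 0.5) * pitch)
  row_top <- top + (seq_len(nr) - 1L) * (len + config$row_gap_px) +
    round(config$row_gap_px / 2)

  grid <- expand.grid(column = seq_len(nc), row = seq_len(nr))
  x_min <- col_centre[grid$column] - half_w
  y_min <- row_top[grid$row]
  # background rectangle midpoint: toward the next column, or the
  # previous one for the outermost column
  bg_mid <- ifelse(grid$column < nc,
                   (col_centre[grid$column] + col_centre[pmin(grid$column + 1L, nc)]) / 2,
                   (col_centre[pmax(grid$column - 1L, 1L)] + col_centre[grid$column]) / 2)
  tubes <- tibble::tibble(
    tube_id = seq_len(nrow(grid)),
    column = grid$column, row = grid$row,
    x_min = as.integer(x_min), x_max = as.integer(x_min + wid - 1L),
    y_min = as.integer(y_min), y_max = as.integer(y_min + len - 1L),
    bg_x_min = as.integer(round(bg_mid) - 2L),
    bg_x_max = as.integer(round(bg_mid) + 2L),
    bg_y_min = as.integer(y_min), bg_y_max = as.integer(y_min + len - 1L)
  )

  markers <- rbind(
    c(min(tubes$x_min) - 30, min(tubes$y_min) - 16),   # top-left
    c(max(tubes$x_max) + 30, min(tubes$y_min) - 16),   # top-right
    c(min(tubes$x_min) - 30, max(tubes$y_max) + 16)    # bottom-left
  )
  markers[, 1] <- pmin(pmax(markers[, 1], 6), W - 5)
  markers[, 2] <- pmin(pmax(markers[, 2], 6), H - 5)
  colnames(markers) <- c("x", "y")

  structure(list(tubes = tubes, marker_points = markers, rotation_deg = 0,
                 image_size = c(W, H), n_bins = config$n_bins),
            class = "tray_geometry")
}

#' @export
print.tray_geometry <- function(x, ...) {
  cat(sprintf("<tray_geometry> %d tubes, image %d x %d px, rotation %.3f deg\n",
              nrow(x$tubes), x$image_size[1], x$image_size[2], x$rotation_deg))
  invisible(x)
}

# deposit an integrated Gaussian spot (total counts) onto a matrix [y, x]
add_spot <- function(mat, x0, y0, sigma, total) {
  if (total <= 0) return(mat)
  r <- max(4L, ceiling(4 * sigma))
  xs <- max(1L, floor(x0) - r):min(ncol(mat), ceiling(x0) + r)
  ys <- max(1L, floor(y0) - r):min(nrow(mat), ceiling(y0) + r)
  wx <- diff(stats::pnorm(c(xs[1] - 0.5, xs + 0.5), x0, sigma))
  wy <- diff(stats::pnorm(c(ys[1] - 0.5, ys + 0.5), y0, sigma))
  mat[ys, xs] <- mat[ys, xs] + total * (wy %o% wx)
  mat
}

# smooth radial vignette field, 1 at centre
vignette_field <- function(W, H, gain) {
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  r2 <- outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, `+`)
  1 - gain * r2 / max(r2)
}

#' Render a synthetic frame stack
#'
#' Composes, per 300-s frame: the vignette-scaled camera background; a
#' faint uniform glow inside each tube (capillary scatter); three bright
#' corner marker spots; and each fly's photons. A resting fly deposits
#' `rate x dwell` counts as a compact Gaussian spot at its bin; an
#' active fly smears its photons across the bins it visited, in
#' proportion to dwell time, so photon count is conserved per frame up
#' to PSF truncation. Optionally the whole scene is rotated about the
#' image centre before noise, to exercise the alignment step. With shot
#' noise on, pixel values are Poisson draws plus Gaussian read noise,
#' rounded and clipped to the 16-bit range.
#'
#' @param config A [sim_config()].
#' @param truths Optional list of [simulate_behaviour()] results, one per
#'   tube (simulated from `config` if omitted).
#' @param clock Optional list of [simulate_clock()] tibbles, one per tube.
#' @return A `frame_stack`: list with `frames` (list of integer
#'   matrices, `[y, x]`), `t_h`, `frame_s`, `geometry` (true, aligned
#'   orientation; `marker_points` are the positions as rendered, i.e.
#'   after rotation), `applied_rotation_deg`, `truth` (list with
#'   `flies`, `clock`), `saturated` flag and `config`.
#' @export
render_stack <- function(config, truths = NULL, clock = NULL) {
  stopifnot(inherits(config, "sim_config"))
  geom <- sim_layout(config)
  n_flies <- config$n_flies
  if (is.null(truths))
    truths <- lapply(seq_len(n_flies), function(i) simulate_behaviour(config, i))
  if (length(truths) != n_flies)
    stop("need one behavioural truth per tube", call. = FALSE)
  if (is.null(clock))
    clock <- lapply(seq_len(n_flies), function(i) simulate_clock(config, i))

  W <- config$image_size[1]; H <- config$image_size[2]
  static <- config$background_level * vignette_field(W, H, config$vignette_gain)
  for (i in seq_len(n_flies)) {
    tb <- geom$tubes[i, ]
    static[tb$y_min:tb$y_max, tb$x_min:tb$x_max] <-
      static[tb$y_min:tb$y_max, tb$x_min:tb$x_max] + config$tube_glow
  }
  for (k in seq_len(3))
    static <- add_spot(static, geom$marker_points[k, 1], geom$marker_points[k, 2],
                       1.5, config$marker_level)

  rot <- config$rotation_deg
  markers_rendered <- if (rot != 0)
    rotate_points(geom$marker_points, rot, c(W, H)) else geom$marker_points

  # pre-split dwell tables by frame for speed
  dwell_by_frame <- lapply(truths, function(tr)
    split(tr$dwell[c("bin", "seconds")], tr$dwell$frame))
  rates <- vapply(clock, function(cl) cl$photon_rate, numeric(config$n_frames))
  if (config$n_frames == 1) rates <- matrix(rates, nrow = 1)

  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(fly_seeds(config)[n_flies + 1L])

  saturated <- FALSE
  frames <- vector("list", config$n_frames)
  for (f in seq_len(config$n_frames)) {
    S <- static
    for (i in seq_len(n_flies)) {
      tb <- geom$tubes[i, ]
      xc <- (tb$x_min + tb$x_max) / 2
      dw <- dwell_by_frame[[i]][[as.character(f)]]
      if (is.null(dw)) next
      for (j in seq_len(nrow(dw))) {
        yc <- tb$y_min + (dw$bin[j] - 0.5) * 4 - 0.5
        S <- add_spot(S, xc, yc, config$psf_sigma_px,
                      rates[f, i] * dw$seconds[j])
      }
    }
    if (rot != 0) S <- rotate_frame(S, rot)
    if (any(S > 65535)) saturated <- TRUE
    X <- if (config$shot_noise) stats::rpois(length(S), pmax(S, 0)) else S
    if (config$read_noise_sd > 0)
      X <- X + stats::rnorm(length(S), 0, config$read_noise_sd)
    frames[[f]] <- matrix(as.integer(pmin(pmax(round(X), 0), 65535)), H, W)
  }
  if (saturated)
    warning("expected intensity exceeded the 16-bit range; frames are clipped",
            call. = FALSE)

  geom$marker_points <- markers_rendered
  structure(
    list(frames = frames,
         t_h = (seq_len(config$n_frames) - 0.5) * config$frame_s / 3600,
         frame_s = config$frame_s, image_size = c(W, H),
         geometry = geom, applied_rotation_deg = rot,
         truth = list(flies = truths, clock = clock),
         saturated = saturated, config = config),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %g s each%s\n",
              length(x$frames), x$image_size[1], x$image_size[2], x$frame_s,
              if (x$applied_rotation_deg != 0)
                sprintf(", rendered rotation %.2f deg", x$applied_rotation_deg) else ""))
  invisible(x)
}

#' Write / read a frame stack as multi-page 16-bit TIFF plus JSON sidecar
#'
#' The sidecar carries timestamps, geometry and (for synthetic stacks)
#' the ground truth, so a written stack round-trips through
#' [read_stack()].
#'
#' @param stack A `frame_stack`.
#' @param tif_path Output TIFF path.
#' @param sidecar_path Output JSON path (default: `tif_path` with a
#'   `.json` extension).
#' @return `write_stack()` returns the paths invisibly; `read_stack()`
#'   returns a `frame_stack`.
#' @export
write_stack <- function(stack, tif_path, sidecar_path = sub("\\.tiff?$", ".json", tif_path)) {
  stopifnot(inherits(stack, "frame_stack"))
  tiff::writeTIFF(lapply(stack$frames, function(m) m / 65535), tif_path,
                  bits.per.sample = 16L)
  side <- list(
    frame_s = stack$frame_s, t_h = stack$t_h, image_size = stack$image_size,
    applied_rotation_deg = stack$applied_rotation_deg,
    geometry = geometry_to_list(stack$geometry),
    saturated = stack$saturated
  )
  if (!is.null(stack$truth)) {
    side$truth <- list(
      flies = lapply(stack$truth$flies, function(tr)
        list(fly_id = tr$fly_id, scenario = tr$scenario,
             true_period_h = tr$true_period_h,
             frames = tr$frames, episodes = tr$episodes)),
      clock = stack$truth$clock
    )
  }
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(tif_path, sidecar_path))
}

#' @rdname write_stack
#' @param tif_path,sidecar_path Paths written by [write_stack()].
#' @export
read_stack <- function(tif_path, sidecar_path = sub("\\.tiff?$", ".json", tif_path)) {
  frames <- tiff::readTIFF(tif_path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  truth <- NULL
  if (!is.null(side$truth)) {
    truth <- list(
      flies = lapply(seq_along(side$truth$flies$fly_id %||% side$truth$flies),
                     function(i) {
        fl <- if (is.data.frame(side$truth$flies)) side$truth$flies[i, ] else side$truth$flies[[i]]
        structure(list(fly_id = fl$fly_id, scenario = fl$scenario,
                       true_period_h = fl$true_period_h,
                       frames = tibble::as_tibble(as.data.frame(fl$frames)),
                       episodes = tibble::as_tibble(as.data.frame(fl$episodes)),
                       dwell = NULL),
                  class = "fly_truth")
      }),
      clock = lapply(side$truth$clock, function(cl)
        tibble::as_tibble(as.data.frame(cl)))
    )
  }
  structure(
    list(frames = frames, t_h = side$t_h, frame_s = side$frame_s,
         image_size = side$image_size,
         geometry = list_to_geometry(side$geometry),
         applied_rotation_deg = side$applied_rotation_deg,
         truth = truth, saturated = isTRUE(side$saturated), config = NULL),
    class = "frame_stack"
  )
}

geometry_to_list <- function(geom) {
  list(tubes = geom$tubes,
       marker_points = if (is.null(geom$marker_points)) NULL else
         as.data.frame(geom$marker_points),
       rotation_deg = geom$rotation_deg,
       image_size = geom$image_size, n_bins = geom$n_bins)
}

list_to_geometry <- function(x) {
  if (is.null(x)) return(NULL)
  mp <- NULL
  if (!is.null(x$marker_points) && length(x$marker_points)) {
    mp <- as.matrix(as.data.frame(x$marker_points))
    colnames(mp) <- c("x", "y")
  }
  structure(list(tubes = tibble::as_tibble(as.data.frame(x$tubes)),
                 marker_points = mp, rotation_deg = x$rotation_deg,
                 image_size = unlist(x$image_size), n_bins = x$n_bins),
            class = "tray_geometry")
}

#' Export per-fly per-frame ground truth as CSV
#'
#' @param stack A synthetic `frame_stack` (with `truth`).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_truth_csv <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"), !is.null(stack$truth))
  tab <- dplyr::bind_rows(lapply(stack$truth$flies, function(tr)
    dplyr::mutate(tr$frames, fly_id = tr$fly_id,
                  true_period_h = tr$true_period_h, .before = 1)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
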
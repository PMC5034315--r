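#' Percentile-clipped linear contrast stretch
#'
#' Monotone remap of a globally background-subtracted frame to the full
#' 16-bit dynamic range: intensities at or below the lower percentile
#' map to 0, at or above the upper percentile to 65535, linearly in
#' between. The defaults stretch from the frame median (the camera
#' background, which occupies most of a sparse bioluminescence scene,
#' collapses to 0) to the frame maximum (fly spots keep their shape
#' instead of saturating, which the resting-peak rule depends on).
#' Used only to make resting-fly spots easy to detect; all quantitative
#' measures run on the raw data. Frames differing by a positive affine
#' transform produce identical enhanced output.
#'
#' @param frame Numeric matrix.
#' @param lower,upper Clipping percentiles (fractions).
#' @return Numeric matrix in `[0, 65535]`. A constant input is returned
#'   unchanged with attribute `constant = TRUE`.
#' @export
enhance_contrast <- function(frame, lower = 0.5, upper = 1) {
  q <- stats::quantile(frame, c(lower, upper), names = FALSE)
  if (q[2] <= q[1]) {
    attr(frame, "constant") <- TRUE
    return(frame)
  }
  out <- (frame - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0; out[out > 1] <- 1
  out * 65535
}

#' Binned intensity profile of one tube
#'
#' Divides the tube rectangle (17 px wide) into 4-px-high bins along the
#' tube's long axis (46 bins for the standard 184-px tube) and records,
#' per bin, the summed pixel intensity and the maximum single-pixel
#' intensity, after subtracting the tube's local background. Also
#' carries the mean and standard deviation of the bin sums, which feed
#' the resting-peak rule.
#'
#' @param frame Numeric matrix (globally background-subtracted; negative
#'   values are retained so sums stay unbiased).
#' @param geometry A `tray_geometry`.
#' @param tube_id Tube index.
#' @param local_bg Local background counts per pixel; computed with
#'   [local_background()] when `NULL`. Pass 0 for the enhanced-data path.
#' @return A `tube_profile`: list with `bin_sum`, `bin_max`,
#'   `tube_mean`, `tube_sd`, `local_bg`, `n_bins`.
#' @export
profile_tube <- function(frame, geometry, tube_id, local_bg = NULL) {
  tb <- geometry$tubes[geometry$tubes$tube_id == tube_id, ]
  if (nrow(tb) != 1) stop("unknown tube_id: ", tube_id, call. = FALSE)
  n_bins <- geometry$n_bins
  if (tb$y_max - tb$y_min + 1L != n_bins * 4L)
    stop(sprintf("tube %d spans %d px; geometry requires %d (= %d bins of 4 px)",
                 tube_id, tb$y_max - tb$y_min + 1L, n_bins * 4L, n_bins),
         call. = FALSE)
  if (is.null(local_bg)) local_bg <- local_background(frame, geometry, tube_id)
  px <- frame[tb$y_min:tb$y_max, tb$x_min:tb$x_max, drop = FALSE] - local_bg
  bin_of <- rep(seq_len(n_bins), each = 4L)
  bin_sum <- as.vector(rowsum(rowSums(px), bin_of))
  bin_max <- as.vector(tapply(apply(px, 1, max), bin_of, max))
  structure(list(bin_sum = bin_sum, bin_max = bin_max,
                 tube_mean = mean(bin_sum), tube_sd = stats::sd(bin_sum),
                 local_bg = local_bg, n_bins = n_bins),
            class = "tube_profile")
}

#' Resting-fly peaks in an enhanced tube profile
#'
#' A bin contains a resting fly when its maximum single-pixel intensity
#' strictly exceeds the tube's mean bin intensity plus one standard
#' deviation. Runs of adjacent flagged bins merge into one peak (a
#' single sub-threshold bin separates peaks); each peak's anchor is the
#' intensity-weighted centroid of its bins.
#'
#' @param profile A `tube_profile` computed from the enhanced frame.
#' @return Tibble with `start_bin`, `end_bin`, `anchor_bin`, `area`
#'   (summed bin intensity); zero rows when no bin passes the rule.
#' @export
detect_rest_peaks <- function(profile) {
  stopifnot(inherits(profile, "tube_profile"))
  thr <- profile$tube_mean + profile$tube_sd
  flagged <- profile$bin_max > thr
  if (!any(flagged))
    return(tibble::tibble(start_bin = integer(), end_bin = integer(),
                          anchor_bin = numeric(), area = numeric()))
  r <- rle(flagged)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  purrr::map_dfr(runs, function(i) {
    bins <- starts[i]:ends[i]
    w <- pmax(profile$bin_sum[bins], 0)
    anchor <- if (sum(w) > 0) sum(bins * w) / sum(w) else mean(bins)
    tibble::tibble(start_bin = starts[i], end_bin = ends[i],
                   anchor_bin = anchor, area = sum(profile$bin_sum[bins]))
  })
}

#' Partition a frame's exposure time into activity and rest
#'
#' The smear of an active fly appears as a rectangle of height
#' "mean-without-peaks" (the mean raw bin sum excluding peak bins) over
#' the whole tube; each resting peak contributes its area above that
#' level. The 300 s of exposure are split in proportion:
#' `time_active = frame_s * A_active / (A_active + A_rest)` and
#' `time_rest = frame_s - time_active`, so the two always sum to the
#' frame length exactly. A negative mean-without-peaks (artefactual
#' background) or a total area of zero (fly too dim) flags the frame as
#' bad instead of yielding times; bad frames are later interpolated.
#'
#' @param raw_profile A `tube_profile` from the raw (background-
#'   subtracted) frame.
#' @param peaks Peak tibble from [detect_rest_peaks()] (run on the
#'   enhanced profile).
#' @param frame_s Exposure seconds.
#' @return One-row tibble: `time_active_s`, `time_rest_s`, `n_peaks`,
#'   `anchor_bin` (anchor of the largest peak, `NA` if none), `anchors`
#'   (list column of all anchors), `quality` in ok/negative_mean/too_dim.
#' @export
partition_frame_time <- function(raw_profile, peaks, frame_s = 300) {
  stopifnot(inherits(raw_profile, "tube_profile"))
  peak_bins <- if (nrow(peaks))
    unlist(purrr::map2(peaks$start_bin, peaks$end_bin, seq)) else integer()
  non_peak <- setdiff(seq_len(raw_profile$n_bins), peak_bins)
  mwp <- if (length(non_peak)) mean(raw_profile$bin_sum[non_peak]) else 0

  n_peaks <- nrow(peaks)
  anchor <- if (n_peaks) peaks$anchor_bin[which.max(peaks$area)] else NA_real_
  anchors <- list(peaks$anchor_bin)

  if (mwp < 0)
    return(tibble::tibble(time_active_s = NA_real_, time_rest_s = NA_real_,
                          n_peaks = n_peaks, anchor_bin = anchor,
                          anchors = anchors, quality = "negative_mean"))
  a_active <- mwp * raw_profile$n_bins
  a_rest <- sum(pmax(raw_profile$bin_sum[peak_bins] - mwp, 0))
  if (a_active + a_rest <= 0)
    return(tibble::tibble(time_active_s = NA_real_, time_rest_s = NA_real_,
                          n_peaks = n_peaks, anchor_bin = anchor,
                          anchors = anchors, quality = "too_dim"))
  t_act <- min(max(frame_s * a_active / (a_active + a_rest), 0), frame_s)
  tibble::tibble(time_active_s = t_act, time_rest_s = frame_s - t_act,
                 n_peaks = n_peaks, anchor_bin = anchor,
                 anchors = anchors, quality = "ok")
}

#' Total background-adjusted bioluminescence of a tube
#'
#' Sum of pixel intensities over the tube rectangle after global and
#' local background subtraction: the molecular-clock signal, reporting
#' clock-gene expression in the fly's peripheral tissues.
#'
#' @inheritParams profile_tube
#' @return Scalar counts.
#' @export
tube_bioluminescence <- function(frame, geometry, tube_id, local_bg = NULL) {
  tb <- geometry$tubes[geometry$tubes$tube_id == tube_id, ]
  if (nrow(tb) != 1) stop("unknown tube_id: ", tube_id, call. = FALSE)
  if (is.null(local_bg)) local_bg <- local_background(frame, geometry, tube_id)
  sum(frame[tb$y_min:tb$y_max, tb$x_min:tb$x_max] - local_bg)
}

#' Quantify every tube of every frame of an aligned stack
#'
#' Per frame: estimates and subtracts the global background, builds the
#' contrast-enhanced copy for peak detection, and then, per tube,
#' measures the local background, the raw and enhanced bin profiles,
#' the resting peaks, the active/rest time partition and the total
#' bioluminescence.
#'
#' @param stack An aligned `frame_stack`.
#' @param geometry A `tray_geometry`; defaults to the stack's own
#'   (simulator truth). Use [detect_tubes()] output for real data.
#' @param enhance_quantiles Percentiles for [enhance_contrast()].
#' @return Tibble with one row per fly per frame: `fly_id`, `frame`,
#'   `t_h`, `time_active_s`, `time_rest_s`, `n_peaks`, `anchor_bin`,
#'   `anchors` (list), `biolum`, `quality`.
#' @export
quantify_stack <- function(stack, geometry = NULL,
                           enhance_quantiles = c(0.5, 1)) {
  stopifnot(inherits(stack, "frame_stack"))
  geom <- geometry %||% stack$geometry
  if (is.null(geom)) stop("no tray geometry available", call. = FALSE)
  ids <- geom$tubes$tube_id
  local_bgs <- numeric(length(ids))

  res <- vector("list", length(stack$frames))
  for (f in seq_along(stack$frames)) {
    fr <- stack$frames[[f]]
    fr <- fr - estimate_global_background(fr)
    enh <- enhance_contrast(fr, enhance_quantiles[1], enhance_quantiles[2])
    rows <- vector("list", length(ids))
    for (k in seq_along(ids)) {
      id <- ids[k]
      lb <- local_background(fr, geom, id)
      rawp <- profile_tube(fr, geom, id, local_bg = lb)
      enhp <- profile_tube(enh, geom, id, local_bg = 0)
      peaks <- detect_rest_peaks(enhp)
      part <- partition_frame_time(rawp, peaks, frame_s = stack$frame_s)
      part$fly_id <- id
      part$biolum <- sum(rawp$bin_sum)
      rows[[k]] <- part
    }
    out <- dplyr::bind_rows(rows)
    out$frame <- f
    out$t_h <- stack$t_h[f]
    res[[f]] <- out
  }
  dplyr::relocate(dplyr::bind_rows(res), "fly_id", "frame", "t_h")
}

#' Interpolate bad frames in a quantified series
#'
#' Frames flagged `negative_mean` or `too_dim` get their activity/rest
#' partition and bioluminescence replaced by linear interpolation
#' between the nearest good frames (nearest-value fill at the ends).
#'
#' @param partitions Tibble from [quantify_stack()].
#' @return The tibble with bad frames filled in and a logical
#'   `interpolated` column added.
#' @export
interpolate_bad_frames <- function(partitions) {
  fix_fly <- function(df) {
    bad <- df$quality != "ok"
    if (all(bad))
      stop("all frames are bad for fly ", df$fly_id[1], call. = FALSE)
    df$interpolated <- bad
    if (any(bad)) {
      for (col in c("time_active_s", "time_rest_s", "biolum")) {
        x <- df[[col]]
        x[bad] <- NA_real_
        df[[col]] <- zoo::na.approx(x, x = df$frame, na.rm = FALSE, rule = 2)
      }
    }
    df
  }
  grp <- factor(partitions$fly_id, levels = unique(partitions$fly_id))
  dplyr::bind_rows(lapply(split(partitions, grp), fix_fly))
}

#' @rdname interpolate_bad_frames
#' @param series Numeric vector.
#' @param bad Logical vector marking entries to replace.
#' @return `interpolate_series()`: the repaired numeric vector.
#' @export
interpolate_series <- function(series, bad) {
  stopifnot(length(series) == length(bad))
  if (all(bad)) stop("all entries are bad", call. = FALSE)
  series[bad] <- NA_real_
  zoo::na.approx(series, na.rm = FALSE, rule = 2)
}
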
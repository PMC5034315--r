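#' Assign sleep episodes from per-frame partitions
#'
#' Fly sleep is immobility exceeding five minutes. Operationally: a
#' candidate episode is a maximal run of at least two consecutive
#' frames, each containing exactly one resting peak, with every anchor
#' within `anchor_tol` bins of the first frame's anchor (the fly rested
#' at the same position throughout). The run's rest times are summed;
#' when the total exceeds 300 s the whole run is sleep and every one of
#' its frames scores 1 in the binary sleep array. The default is the
#' conservative reading in which continuation frames must themselves be
#' single-peak; with `strict = FALSE` a continuation frame merely needs
#' some peak at the episode position.
#'
#' @param partitions Tibble from [quantify_stack()] (optionally after
#'   [interpolate_bad_frames()]), one fly or several.
#' @param anchor_tol Same-position tolerance in bins (1 bin = 4 px, one
#'   fly length).
#' @param strict Require a single peak in every frame of the episode?
#' @param min_frames Minimum frames per episode.
#' @param min_rest_s Total rest (s) an episode must exceed.
#' @return The input tibble with `sleep_binary` (0/1) and `episode_id`
#'   (per fly, `NA` outside episodes) columns added.
#' @export
assign_sleep_episodes <- function(partitions, anchor_tol = 1, strict = TRUE,
                                  min_frames = 2L, min_rest_s = 300) {
  one_fly <- function(df) {
    n <- nrow(df)
    single <- df$n_peaks == 1 & !is.na(df$anchor_bin)
    near <- function(j, a0) {
      if (strict) return(single[j] && abs(df$anchor_bin[j] - a0) <= anchor_tol)
      any(abs(df$anchors[[j]] - a0) <= anchor_tol)
    }
    sleep <- integer(n)
    epi <- rep(NA_integer_, n)
    n_epi <- 0L
    i <- 1L
    while (i <= n) {
      if (!single[i]) { i <- i + 1L; next }
      a0 <- df$anchor_bin[i]
      j <- i + 1L
      while (j <= n && near(j, a0)) j <- j + 1L
      run <- i:(j - 1L)
      if (length(run) >= min_frames &&
          sum(df$time_rest_s[run], na.rm = TRUE) > min_rest_s) {
        n_epi <- n_epi + 1L
        sleep[run] <- 1L
        epi[run] <- n_epi
      }
      i <- j
    }
    df$sleep_binary <- sleep
    df$episode_id <- epi
    df
  }
  grp <- factor(partitions$fly_id, levels = unique(partitions$fly_id))
  dplyr::bind_rows(lapply(split(partitions, grp), one_fly))
}

#' Summarise sleep episodes
#'
#' @param sleep_df Tibble from [assign_sleep_episodes()].
#' @return Tibble with one row per episode: `fly_id`, `episode_id`,
#'   `start_frame`, `end_frame`, `n_frames`, `duration_s` (summed rest),
#'   `duration_min`, `anchor_bin` (episode-start anchor).
#' @export
sleep_episodes <- function(sleep_df) {
  df <- dplyr::filter(sleep_df, !is.na(.data$episode_id))
  if (!nrow(df))
    return(tibble::tibble(fly_id = integer(), episode_id = integer(),
                          start_frame = integer(), end_frame = integer(),
                          n_frames = integer(), duration_s = numeric(),
                          duration_min = numeric(), anchor_bin = numeric()))
  dplyr::summarise(
    dplyr::group_by(df, .data$fly_id, .data$episode_id),
    start_frame = min(.data$frame), end_frame = max(.data$frame),
    n_frames = dplyr::n(),
    duration_s = sum(.data$time_rest_s),
    duration_min = .data$duration_s / 60,
    anchor_bin = .data$anchor_bin[which.min(.data$frame)],
    .groups = "drop")
}

#' Per-frame sleep consolidation
#'
#' Every frame inside a sleep episode is assigned the duration of its
#' encompassing episode, in minutes; frames outside sleep get 0. The
#' resulting array tracks how long the current block of sleep lasts.
#'
#' @param sleep_df Tibble from [assign_sleep_episodes()].
#' @return The tibble with a `consolidation_min` column added.
#' @export
compute_consolidation <- function(sleep_df) {
  epi <- sleep_episodes(sleep_df)
  out <- dplyr::left_join(sleep_df,
                          epi[c("fly_id", "episode_id", "duration_min")],
                          by = c("fly_id", "episode_id"))
  out$consolidation_min <- ifelse(is.na(out$duration_min), 0, out$duration_min)
  out$duration_min <- NULL
  out
}

#' Bin a per-frame series to 30 minutes
#'
#' Six 300-s frames make one 30-min bin (a trailing partial bin is
#' dropped). `mode = "sum"` is used for times and bioluminescence;
#' `mode = "nonzero_mean"` for sleep consolidation, where a bin's value
#' is the mean of its non-zero entries (0 when all entries are 0);
#' `mode = "mean"` averages all entries.
#'
#' @param series Numeric vector, one value per frame.
#' @param mode One of `"sum"`, `"nonzero_mean"`, `"mean"`.
#' @param frames_per_bin Frames per bin.
#' @return Numeric vector of binned values.
#' @export
bin_30min <- function(series, mode = c("sum", "nonzero_mean", "mean"),
                      frames_per_bin = 6L) {
  mode <- match.arg(mode)
  n_bin <- length(series) %/% frames_per_bin
  if (n_bin == 0) return(numeric(0))
  m <- matrix(series[seq_len(n_bin * frames_per_bin)], nrow = frames_per_bin)
  switch(mode,
    sum = colSums(m),
    mean = colMeans(m),
    nonzero_mean = apply(m, 2, function(x) {
      nz <- x[x != 0]
      if (length(nz)) mean(nz) else 0
    })
  )
}

#' Reduce a quantified, sleep-annotated stack to 30-min series
#'
#' Produces, per fly, the three signals the rhythm analysis consumes:
#' the molecular clock (summed bioluminescence per bin), locomotor
#' activity (percent of bin time spent active) and sleep consolidation
#' (mean non-zero episode length), plus the fraction of sleep frames.
#'
#' @param sleep_df Tibble from [compute_consolidation()].
#' @param frame_s Frame exposure seconds.
#' @param frames_per_bin Frames per 30-min bin.
#' @return Tibble: `fly_id`, `t_h` (bin centres), `pct_active`,
#'   `sleep_fraction`, `consolidation_min`, `biolum`.
#' @export
bin_fly_series <- function(sleep_df, frame_s = 300, frames_per_bin = 6L) {
  need <- c("time_active_s", "sleep_binary", "consolidation_min", "biolum")
  miss <- setdiff(need, names(sleep_df))
  if (length(miss))
    stop("missing columns (run the sleep pipeline first): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bin_h <- frame_s * frames_per_bin / 3600
  one <- function(df) {
    df <- df[order(df$frame), ]
    pct <- 100 * bin_30min(df$time_active_s, "sum", frames_per_bin) /
      (frame_s * frames_per_bin)
    tibble::tibble(
      fly_id = df$fly_id[1],
      t_h = (seq_along(pct) - 0.5) * bin_h,
      pct_active = pct,
      sleep_fraction = bin_30min(df$sleep_binary, "mean", frames_per_bin),
      consolidation_min = bin_30min(df$consolidation_min, "nonzero_mean",
                                    frames_per_bin),
      biolum = bin_30min(df$biolum, "sum", frames_per_bin)
    )
  }
  grp <- factor(sleep_df$fly_id, levels = unique(sleep_df$fly_id))
  dplyr::bind_rows(lapply(split(sleep_df, grp), one))
}
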
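#' Simulate the behavioural ground truth of one fly
#'
#' Generates a two-state (active/rest) semi-Markov trajectory at 10-s
#' resolution over the whole recording. Bout lengths are exponential with
#' means that are sinusoidally modulated over the circadian cycle in the
#' `control` scenario: rest propensity peaks in the early subjective
#' night (long consolidated rest, episodes of several hours are common)
#' and active-bout length peaks twice per cycle, just before subjective
#' dusk and dawn (the classic bimodal activity profile). In `clock_only`
#' and `arrhythmic` scenarios the transition rates are time-homogeneous.
#' While active the fly performs a reflected random walk along the tube;
#' while resting it is stationary, which is what the imaging pipeline
#' later sees as a fixed bright spot.
#'
#' Ground-truth sleep episodes are rest bouts longer than 300 s that
#' intersect at least two frames, matching the operational sleep
#' definition used downstream (immobility exceeding five minutes).
#'
#' @param config A [sim_config()].
#' @param fly_id 1-based fly index; selects a deterministic RNG stream
#'   derived from `config$seed`, so flies are independent and the whole
#'   trajectory is reproducible.
#' @param period_h Behavioural period override (defaults to the fly's
#'   configured period).
#'
#' @return An object of class `fly_truth`: a list with `frames`
#'   (tibble: `frame`, `t_h`, `state` in active/rest/sleep,
#'   `position_bin`, `time_active_s`, `time_rest_s`), `episodes`
#'   (tibble: `start_frame`, `end_frame`, `duration_s`), `dwell`
#'   (tibble: `frame`, `bin`, `seconds` -- photon deposition weights for
#'   the renderer), `true_period_h`, `fly_id` and `scenario`.
#' @export
#' @examples
#' cfg <- sim_config(n_days = 1, n_columns = 1, n_rows = 1,
#'                   image_size = c(128, 256), tube_length_px = 184)
#' tr <- simulate_behaviour(cfg, 1)
#' head(tr$frames)
simulate_behaviour <- function(config, fly_id, period_h = fly_period(config, fly_id)) {
  stopifnot(inherits(config, "sim_config"))
  scenario <- config$behaviour_scenario
  if (!scenario %in% c("control", "clock_only", "arrhythmic"))
    stop("unknown behaviour scenario: ", scenario, call. = FALSE)
  modulated <- scenario == "control"

  dt <- 10                                   # tick, seconds
  ticks_per_frame <- config$frame_s / dt
  if (ticks_per_frame != round(ticks_per_frame))
    stop("`frame_s` must be a multiple of 10 s", call. = FALSE)
  n_ticks <- config$n_frames * ticks_per_frame
  n_bins <- config$n_bins

  mean_rest_s <- function(t_h) {
    if (!modulated) return(config$homog_rest_mean_min * 60)
    config$rest_mean_min * 60 *
      exp(config$rest_mod * cos(2 * pi * (t_h - config$rest_peak_h) / period_h))
  }
  mean_act_s <- function(t_h) {
    if (!modulated) return(config$homog_act_mean_min * 60)
    config$act_mean_min * 60 *
      exp(config$act_mod * cos(4 * pi * (t_h - config$act_peak_h) / period_h))
  }

  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(fly_seeds(config)[fly_id])

  resting <- logical(n_ticks)
  pos <- numeric(n_ticks)
  cur_pos <- stats::runif(1, 0, n_bins)
  cur_rest <- stats::runif(1) < 0.5
  tick <- 0L
  while (tick < n_ticks) {
    t_h <- tick * dt / 3600
    m <- if (cur_rest) mean_rest_s(t_h) else mean_act_s(t_h)
    len <- max(1L, as.integer(round(stats::rexp(1, 1 / m) / dt)))
    len <- min(len, n_ticks - tick)
    idx <- tick + seq_len(len)
    resting[idx] <- cur_rest
    if (cur_rest) {
      pos[idx] <- cur_pos
    } else {
      steps <- stats::rnorm(len, 0, config$step_sd_bins)
      pos[idx] <- reflect_into(cur_pos + cumsum(steps), n_bins)
      cur_pos <- pos[idx[len]]
    }
    cur_rest <- !cur_rest
    tick <- tick + len
  }

  frame_of <- rep(seq_len(config$n_frames), each = ticks_per_frame)
  bin_of <- pmin(floor(pos) + 1L, n_bins)

  # rest bouts -> ground-truth sleep episodes
  r <- rle(resting)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rest_bouts <- tibble::tibble(
    start_tick = starts[r$values], end_tick = ends[r$values],
    duration_s = r$lengths[r$values] * dt
  )
  rest_bouts$start_frame <- frame_of[rest_bouts$start_tick]
  rest_bouts$end_frame <- frame_of[rest_bouts$end_tick]
  episodes <- rest_bouts[rest_bouts$duration_s > 300 &
                           rest_bouts$end_frame > rest_bouts$start_frame,
                         c("start_frame", "end_frame", "duration_s")]

  sleep_tick <- logical(n_ticks)
  keep <- rest_bouts$duration_s > 300 & rest_bouts$end_frame > rest_bouts$start_frame
  for (i in which(keep))
    sleep_tick[rest_bouts$start_tick[i]:rest_bouts$end_tick[i]] <- TRUE

  rest_s <- as.vector(tapply(resting, frame_of, sum)) * dt
  sleep_s <- as.vector(tapply(sleep_tick, frame_of, sum)) * dt
  # majority-dwell bin per frame
  dw <- dplyr::count(tibble::tibble(frame = frame_of, bin = bin_of),
                     .data$frame, .data$bin, name = "ticks")
  dwell <- dplyr::mutate(dw, seconds = .data$ticks * dt, ticks = NULL)
  pos_frame <- dplyr::summarise(dplyr::group_by(dw, .data$frame),
                                position_bin = .data$bin[which.max(.data$ticks)],
                                .groups = "drop")$position_bin

  frames <- tibble::tibble(
    frame = seq_len(config$n_frames),
    t_h = (seq_len(config$n_frames) - 0.5) * config$frame_s / 3600,
    state = dplyr::case_when(
      sleep_s >= config$frame_s / 2 ~ "sleep",
      rest_s >= config$frame_s / 2 ~ "rest",
      TRUE ~ "active"
    ),
    position_bin = pos_frame,
    time_active_s = config$frame_s - rest_s,
    time_rest_s = rest_s
  )

  structure(
    list(fly_id = fly_id, scenario = scenario, true_period_h = period_h,
         frames = frames, episodes = tibble::as_tibble(episodes),
         dwell = dwell),
    class = "fly_truth"
  )
}

# fold a coordinate into [0, L) by reflection at both walls
reflect_into <- function(x, L) {
  y <- x %% (2 * L)
  ifelse(y >= L, 2 * L - y - 1e-9, y)
}

#' Simulate the clock-driven photon rate of one fly
#'
#' The bioluminescence of the clock-protein::luciferase reporter follows
#' `rate(t) = base * 2^(-t/halflife) * (1 + A * cos(2*pi*t/period))`:
#' an exponentially decaying baseline (luciferin consumption) with a
#' circadian modulation that is maximal at subjective dusk (recording
#' start, CT12) and minimal at subjective dawn. In the `arrhythmic`
#' scenario the modulation amplitude is forced to zero.
#'
#' @inheritParams simulate_behaviour
#' @param period_h Clock period override, hours.
#' @return Tibble with `frame`, `t_h` (frame-centre hours since
#'   recording start) and `photon_rate` (counts/s).
#' @export
simulate_clock <- function(config, fly_id, period_h = fly_period(config, fly_id)) {
  stopifnot(inherits(config, "sim_config"))
  amp <- if (config$behaviour_scenario == "arrhythmic") 0 else config$clock_amplitude
  t_h <- (seq_len(config$n_frames) - 0.5) * config$frame_s / 3600
  rate <- config$base_photon_rate * 2^(-t_h / config$decay_halflife_h) *
    (1 + amp * cos(2 * pi * t_h / period_h))
  tibble::tibble(frame = seq_len(config$n_frames), t_h = t_h, photon_rate = rate)
}
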
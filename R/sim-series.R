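#' Simulate one fly's 30-min-binned signal triplet from ground truth
#'
#' Generates the clock, locomotor and sleep-consolidation series a
#' perfectly measured fly would produce, without rendering or image
#' processing: bioluminescence is the clock photon rate integrated per
#' frame (Poisson counting noise when `config$shot_noise` is on),
#' locomotor activity and consolidation come from the behavioural
#' ground truth. The clock and behaviour may be given different true
#' periods, which is how coupled- and uncoupled-period cohorts are
#' built.
#'
#' @param config A [sim_config()].
#' @param fly_id Fly index (selects the deterministic RNG streams).
#' @param clock_period_h,behaviour_period_h True periods of the two
#'   generators, hours.
#' @param frames_per_bin Frames per 30-min bin.
#' @return Tibble: `fly_id`, `t_h`, `pct_active`, `consolidation_min`,
#'   `biolum`, plus attributes `true_clock_period_h`,
#'   `true_behaviour_period_h`.
#' @export
simulate_fly_series <- function(config, fly_id,
                                clock_period_h = fly_period(config, fly_id),
                                behaviour_period_h = fly_period(config, fly_id),
                                frames_per_bin = 6L) {
  tr <- simulate_behaviour(config, fly_id, period_h = behaviour_period_h)
  cl <- simulate_clock(config, fly_id, period_h = clock_period_h)

  counts <- cl$photon_rate * config$frame_s
  if (config$shot_noise) {
    old_seed <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(fly_seeds(config, 2L * config$n_flies + 2L)[config$n_flies + fly_id])
    counts <- stats::rpois(length(counts), counts)
  }

  consol <- numeric(config$n_frames)
  if (nrow(tr$episodes))
    for (i in seq_len(nrow(tr$episodes)))
      consol[tr$episodes$start_frame[i]:tr$episodes$end_frame[i]] <-
        tr$episodes$duration_s[i] / 60

  bin_h <- config$frame_s * frames_per_bin / 3600
  pct <- 100 * bin_30min(tr$frames$time_active_s, "sum", frames_per_bin) /
    (config$frame_s * frames_per_bin)
  out <- tibble::tibble(
    fly_id = fly_id,
    t_h = (seq_along(pct) - 0.5) * bin_h,
    pct_active = pct,
    consolidation_min = bin_30min(consol, "nonzero_mean", frames_per_bin),
    biolum = bin_30min(counts, "sum", frames_per_bin)
  )
  attr(out, "true_clock_period_h") <- clock_period_h
  attr(out, "true_behaviour_period_h") <- behaviour_period_h
  out
}

#' Simulate a cohort of binned signal triplets
#'
#' Per-fly true periods are drawn about `centre_h`: a shared per-fly
#' modifier (SD `shared_sd_h`, sized like a period-mutant spread so it dominates single-fly period-estimation noise) plus independent per-signal jitter (SD
#' `indep_sd_h`). With `coupling = "coupled"` the shared modifier moves
#' the clock and behaviour periods together (period correlation should
#' be detected); with `"uncoupled"` the two signals draw independent
#' modifiers (no correlation to find).
#'
#' @param config A [sim_config()] (its `seed` and `n_flies` drive the
#'   cohort; use `n_columns`/`n_rows` to set cohort size).
#' @param coupling `"coupled"` or `"uncoupled"`.
#' @param centre_h Cohort mean period, hours.
#' @param shared_sd_h SD of the per-fly period modifier, hours.
#' @param indep_sd_h SD of per-signal independent jitter, hours.
#' @return Tibble of stacked [simulate_fly_series()] outputs with a
#'   `truth` attribute (tibble of per-fly true periods).
#' @export
simulate_cohort_series <- function(config,
                                   coupling = c("coupled", "uncoupled"),
                                   centre_h = 24, shared_sd_h = 1.5,
                                   indep_sd_h = 0.15) {
  coupling <- match.arg(coupling)
  n <- config$n_flies
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(fly_seeds(config, 2L * n + 2L)[2L * n + 2L])
  shared_clock <- stats::rnorm(n, 0, shared_sd_h)
  shared_beh <- if (coupling == "coupled") shared_clock
                else stats::rnorm(n, 0, shared_sd_h)
  clock_p <- centre_h + shared_clock + stats::rnorm(n, 0, indep_sd_h)
  beh_p <- centre_h + shared_beh + stats::rnorm(n, 0, indep_sd_h)

  out <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    simulate_fly_series(config, i, clock_period_h = clock_p[i],
                        behaviour_period_h = beh_p[i])))
  attr(out, "truth") <- tibble::tibble(fly_id = seq_len(n),
                                       true_clock_period_h = clock_p,
                                       true_behaviour_period_h = beh_p)
  out
}
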
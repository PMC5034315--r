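#' Simulation configuration for synthetic frame stacks
#'
#' Builds the parameter set that drives the synthetic imaging pipeline:
#' tray layout, camera model, photon budget of the luciferase reporter,
#' and the behavioural scenario. Defaults describe the standard recording:
#' 7 days of contiguous 300-s integrations of a 1024x1024 16-bit camera,
#' flies free-running in constant darkness starting at subjective dusk
#' (CT12), bioluminescence highest at subjective dusk and decaying
#' exponentially as the luciferin substrate is consumed.
#'
#' @param n_days Recording length in days.
#' @param frame_s Integration time per frame in seconds.
#' @param image_size Integer vector `c(width, height)` in pixels.
#' @param n_columns,n_rows Tube layout (at most 48 tubes per tray).
#' @param tube_length_px Tube length in pixels (46 bins of 4 px).
#' @param tube_width_px Tube width in pixels.
#' @param column_pitch_px Centre-to-centre spacing of tube columns; must
#'   leave room for the 5-px inter-tube background rectangles.
#' @param row_gap_px Vertical gap between tube rows.
#' @param period_h True circadian period of the fly, hours. May be a
#'   vector (recycled per fly) to give flies individual periods.
#' @param clock_amplitude Relative modulation depth of the clock-driven
#'   bioluminescence, in `[0, 1]`.
#' @param decay_halflife_h Luciferin-decay half-life in hours (`Inf` for a
#'   stationary baseline).
#' @param base_photon_rate Fly photon rate at time zero, counts/s.
#' @param psf_sigma_px Gaussian width of a resting fly's spot, pixels.
#' @param background_level Camera background, counts/frame/pixel, scaled
#'   by the vignette field.
#' @param vignette_gain Strength of the radial multiplicative vignette
#'   (0 = flat field).
#' @param tube_glow Uniform in-tube baseline from capillary scatter,
#'   counts/frame/pixel. This is what keeps the tube interior slightly
#'   brighter than the inter-tube background regions.
#' @param marker_level Peak intensity of the three corner marker spots,
#'   counts/frame.
#' @param read_noise_sd Gaussian read noise standard deviation, counts.
#' @param shot_noise Apply Poisson shot noise to all emitted light?
#' @param rotation_deg Global tray rotation baked into rendered frames,
#'   degrees (exercises the alignment step).
#' @param behaviour_scenario One of `"control"` (circadianly modulated
#'   behaviour and clock), `"clock_only"` (time-homogeneous behaviour,
#'   cycling clock) or `"arrhythmic"` (both time-homogeneous).
#' @param rest_mean_min,rest_mod Baseline mean rest-bout length (minutes)
#'   and the exponent of its sinusoidal circadian modulation: the mean
#'   rest bout at circadian time `t` hours after dusk is
#'   `rest_mean_min * exp(rest_mod * cos(2*pi*(t - rest_peak_h)/period))`.
#' @param rest_peak_h Phase (hours after subjective dusk) of maximal rest
#'   propensity (early subjective night).
#' @param act_mean_min,act_mod Baseline mean active-bout length (minutes)
#'   and the exponent of its twice-daily modulation, peaking just before
#'   subjective dusk and dawn.
#' @param act_peak_h Phase (hours after dusk) of the morning activity
#'   peak; the evening peak sits half a cycle away.
#' @param homog_rest_mean_min,homog_act_mean_min Mean rest/active bout
#'   lengths (minutes) for the time-homogeneous scenarios (`clock_only`,
#'   `arrhythmic`): dysrhythmic flies are restless, with short
#'   fragmented rest bouts spread evenly over the day.
#' @param step_sd_bins Random-walk step of an active fly per 10-s tick,
#'   in tube bins.
#' @param seed Integer seed; all per-fly RNG streams derive from it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_days = 2, n_columns = 4, n_rows = 1,
#'                   image_size = c(256, 256))
#' cfg$n_frames
sim_config <- function(n_days = 7,
                       frame_s = 300,
                       image_size = c(1024, 1024),
                       n_columns = 12,
                       n_rows = 4,
                       tube_length_px = 184,
                       tube_width_px = 17,
                       column_pitch_px = 32,
                       row_gap_px = 24,
                       period_h = 24,
                       clock_amplitude = 0.4,
                       decay_halflife_h = 70,
                       base_photon_rate = 20,
                       psf_sigma_px = 0.6,
                       background_level = 5,
                       vignette_gain = 0.25,
                       tube_glow = 0.15,
                       marker_level = 3000,
                       read_noise_sd = 1.5,
                       shot_noise = TRUE,
                       rotation_deg = 0,
                       behaviour_scenario = c("control", "clock_only", "arrhythmic"),
                       rest_mean_min = 32,
                       rest_mod = 0.84,
                       rest_peak_h = 3,
                       act_mean_min = 4,
                       act_mod = 1.6,
                       act_peak_h = 11.5,
                       homog_rest_mean_min = 10,
                       homog_act_mean_min = 4,
                       step_sd_bins = 12,
                       seed = 1L) {
  behaviour_scenario <- match.arg(behaviour_scenario)
  stopifnot(
    n_days > 0, frame_s > 0,
    length(image_size) == 2, all(image_size > 0),
    tube_length_px > 0, tube_width_px > 0,
    all(period_h > 0), decay_halflife_h > 0,
    base_photon_rate >= 0, psf_sigma_px > 0,
    background_level >= 0, read_noise_sd >= 0, marker_level >= 0,
    tube_glow >= 0, rest_mean_min > 0, act_mean_min > 0, step_sd_bins > 0,
    homog_rest_mean_min > 0, homog_act_mean_min > 0
  )
  if (clock_amplitude < 0 || clock_amplitude > 1)
    stop("`clock_amplitude` must lie in [0, 1]", call. = FALSE)
  if (n_columns * n_rows > 48)
    stop("a tray holds at most 48 tubes (n_columns * n_rows <= 48)", call. = FALSE)
  if (column_pitch_px < tube_width_px + 7)
    stop("`column_pitch_px` too small for 5-px background rectangles between tubes",
         call. = FALSE)

  cfg <- list(
    n_days = n_days, frame_s = frame_s,
    image_size = as.integer(image_size),
    n_columns = as.integer(n_columns), n_rows = as.integer(n_rows),
    tube_length_px = as.integer(tube_length_px),
    tube_width_px = as.integer(tube_width_px),
    column_pitch_px = as.integer(column_pitch_px),
    row_gap_px = as.integer(row_gap_px),
    period_h = period_h, clock_amplitude = clock_amplitude,
    decay_halflife_h = decay_halflife_h,
    base_photon_rate = base_photon_rate, psf_sigma_px = psf_sigma_px,
    background_level = background_level, vignette_gain = vignette_gain,
    tube_glow = tube_glow, marker_level = marker_level,
    read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
    rotation_deg = rotation_deg,
    behaviour_scenario = behaviour_scenario,
    rest_mean_min = rest_mean_min, rest_mod = rest_mod,
    rest_peak_h = rest_peak_h,
    act_mean_min = act_mean_min, act_mod = act_mod, act_peak_h = act_peak_h,
    homog_rest_mean_min = homog_rest_mean_min,
    homog_act_mean_min = homog_act_mean_min,
    step_sd_bins = step_sd_bins,
    seed = as.integer(seed)
  )
  cfg$n_frames <- as.integer(round(n_days * 86400 / frame_s))
  cfg$n_bins <- as.integer(tube_length_px / 4L)
  cfg$n_flies <- cfg$n_columns * cfg$n_rows
  class(cfg) <- "sim_config"

  layout_w <- 2L * 40L + n_columns * column_pitch_px
  layout_h <- 2L * 30L + n_rows * (tube_length_px + row_gap_px)
  if (layout_w > image_size[1] || layout_h > image_size[2])
    stop(sprintf("tray layout (%d x %d px) does not fit in image (%d x %d px)",
                 layout_w, layout_h, image_size[1], image_size[2]), call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d tubes (%d x %d), %g days @ %g s/frame (%d frames)\n",
              x$n_flies, x$n_columns, x$n_rows, x$n_days, x$frame_s, x$n_frames))
  cat(sprintf("  scenario: %s, period %s h, amplitude %.2f, halflife %g h\n",
              x$behaviour_scenario, paste(signif(x$period_h, 4), collapse = "/"),
              x$clock_amplitude, x$decay_halflife_h))
  invisible(x)
}

# deterministic per-fly RNG stream seeds derived from (seed, fly)
fly_seeds <- function(config, n = config$n_flies + 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' True period for one fly under a configuration
#'
#' `period_h` may be scalar or per-fly; this recycles it deterministically.
#' @param config A [sim_config()].
#' @param fly_id 1-based tube/fly index.
#' @return Scalar period in hours.
#' @export
fly_period <- function(config, fly_id) {
  p <- rep(config$period_h, length.out = max(config$n_flies, fly_id))
  p[[fly_id]]
}
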
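# Shared synthetic fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 3 tubes, 1 day: the standard small full-pipeline stack
small_stack <- function() {
  cached("small_stack", function() {
    cfg <- sim_config(n_days = 1, n_columns = 3, n_rows = 1,
                      image_size = c(200, 280), seed = 7)
    align_stack(render_stack(cfg))
  })
}

small_quantified <- function() {
  cached("small_quantified", function() quantify_stack(small_stack()))
}

# noise-free single-frame stack with an immobile fly (conservation tests)
resting_stack <- function() {
  cached("resting_stack", function() {
    cfg <- sim_config(n_days = 1 / 288, n_columns = 2, n_rows = 1,
                      image_size = c(160, 280), seed = 3,
                      shot_noise = FALSE, read_noise_sd = 0,
                      background_level = 0, tube_glow = 0,
                      rest_mean_min = 1e6, act_mean_min = 1e-9)
    render_stack(cfg)
  })
}

# hand-built tube_profile from bin vectors
make_profile <- function(bin_sum, bin_max = bin_sum, local_bg = 0) {
  structure(list(bin_sum = bin_sum, bin_max = bin_max,
                 tube_mean = mean(bin_sum), tube_sd = stats::sd(bin_sum),
                 local_bg = local_bg, n_bins = length(bin_sum)),
            class = "tube_profile")
}

# minimal per-frame partition table for sleep-rule tests
make_partitions <- function(rest_s, n_peaks, anchor,
                            fly_id = 1L, frame_s = 300) {
  n <- length(rest_s)
  tibble::tibble(
    fly_id = fly_id, frame = seq_len(n), t_h = (seq_len(n) - 0.5) * frame_s / 3600,
    time_active_s = frame_s - rest_s, time_rest_s = rest_s,
    n_peaks = n_peaks, anchor_bin = anchor,
    anchors = lapply(anchor, function(a) a[!is.na(a)]),
    biolum = 1000, quality = "ok")
}
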
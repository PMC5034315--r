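test_that("sim_config validates its inputs", {
  expect_error(sim_config(clock_amplitude = 1.2), "amplitude")
  expect_error(sim_config(n_columns = 10, n_rows = 5), "48")
  expect_error(sim_config(n_columns = 12, n_rows = 4, image_size = c(300, 300)),
               "does not fit")
  expect_error(sim_config(base_photon_rate = -1))
  expect_error(sim_config(behaviour_scenario = "jetlag"))
  cfg <- sim_config(n_days = 2)
  expect_equal(cfg$n_frames, 576L)
  expect_equal(cfg$n_bins, 46L)
})

test_that("per-fly periods recycle deterministically", {
  cfg <- sim_config(n_columns = 3, n_rows = 1, image_size = c(200, 280),
                    period_h = c(22, 24, 26))
  expect_equal(sapply(1:3, fly_period, config = cfg), c(22, 24, 26))
})

test_that("behaviour simulation is reproducible and respects invariants", {
  cfg <- sim_config(n_days = 1, n_columns = 3, n_rows = 1,
                    image_size = c(200, 280), seed = 42)
  a <- simulate_behaviour(cfg, 2)
  b <- simulate_behaviour(cfg, 2)
  expect_identical(a$frames, b$frames)
  expect_identical(a$episodes, b$episodes)
  other <- simulate_behaviour(cfg, 3)
  expect_false(identical(a$frames$time_rest_s, other$frames$time_rest_s))

  expect_true(all(a$frames$time_active_s + a$frames$time_rest_s == 300))
  expect_true(all(a$frames$position_bin >= 1 & a$frames$position_bin <= 46))
  if (nrow(a$episodes)) {
    expect_true(all(a$episodes$duration_s > 300))
    expect_true(all(a$episodes$end_frame > a$episodes$start_frame))
  }
})

test_that("control flies sleep long in the early subjective night", {
  # long (>= 3 h) sleep episodes in a subjective-night window for at
  # least half of the flies over a 7-day recording
  cfg <- sim_config(n_days = 7, n_columns = 4, n_rows = 2, seed = 3)
  hits <- vapply(1:8, function(i) {
    ep <- simulate_behaviour(cfg, i)$episodes
    start_h <- (ep$start_frame - 1) * 300 / 3600
    any(ep$duration_s >= 3 * 3600 & (start_h %% 24) < 12)
  }, logical(1))
  expect_gte(mean(hits), 0.5)
})

test_that("arrhythmic behaviour is stationary across circadian phase", {
  cfg <- sim_config(n_days = 7, n_columns = 8, n_rows = 2, seed = 1,
                    behaviour_scenario = "arrhythmic")
  per_fly <- vapply(1:10, function(i) {
    fr <- simulate_behaviour(cfg, i)$frames
    night <- (fr$t_h %% 24) < 12
    diff_s <- mean(fr$time_active_s[night]) - mean(fr$time_active_s[!night])
    ks <- suppressWarnings(stats::ks.test(fr$time_active_s[night],
                                          fr$time_active_s[!night]))$p.value
    c(diff_s, ks)
  }, numeric(2))
  # day/night activity difference centred on zero across flies
  expect_gt(stats::t.test(per_fly[1, ])$p.value, 0.05)
  expect_lt(abs(mean(per_fly[1, ])), 15)
  # per-fly distributional discrepancy is unremarkable in median
  expect_gt(stats::median(per_fly[2, ]), 0.05)
})

test_that("clock photon rate follows the decaying modulated profile", {
  cfg <- sim_config(n_columns = 3, n_rows = 1, image_size = c(200, 280),
                    clock_amplitude = 0, decay_halflife_h = 50)
  cl <- simulate_clock(cfg, 1)
  # pure exponential decay: log-linear in time
  fitted <- stats::lm(log(photon_rate) ~ t_h, data = cl)
  expect_equal(unname(stats::coef(fitted)[2]), -log(2) / 50, tolerance = 1e-10)
  expect_lt(max(abs(stats::resid(fitted))), 1e-10)

  # A = 0.5: after dividing out the decay, max/min ratio is exactly 3
  cfg2 <- sim_config(n_columns = 3, n_rows = 1, image_size = c(200, 280),
                     clock_amplitude = 0.5, decay_halflife_h = 70)
  cl2 <- simulate_clock(cfg2, 1)
  flat <- cl2$photon_rate / 2^(-cl2$t_h / 70)
  expect_equal(max(flat) / min(flat), 3, tolerance = 1e-3)

  # infinite half-life: stationary sinusoid about the base rate
  cfg3 <- sim_config(n_columns = 3, n_rows = 1, image_size = c(200, 280),
                     decay_halflife_h = Inf, clock_amplitude = 0.4)
  cl3 <- simulate_clock(cfg3, 1)
  expect_equal(mean(cl3$photon_rate), cfg3$base_photon_rate, tolerance = 1e-2)
  expect_equal(max(cl3$photon_rate), cfg3$base_photon_rate * 1.4, tolerance = 1e-3)

  # clock phase: maximal at subjective dusk (t = 0), minimal at dawn (t = 12)
  expect_gt(flat[1], flat[which.min(abs(cl2$t_h - 12))])
})

test_that("rendering conserves photons and honours noise switches", {
  st <- resting_stack()
  tb <- st$geometry$tubes[1, ]
  rate <- st$truth$clock[[1]]$photon_rate[1]
  spot <- sum(st$frames[[1]][tb$y_min:tb$y_max, tb$x_min:tb$x_max])
  expect_equal(spot, rate * 300, tolerance = 0.01)

  # zero photons, zero noise, zero background: only markers remain
  cfg0 <- sim_config(n_days = 1 / 288, n_columns = 2, n_rows = 1,
                     image_size = c(160, 280), seed = 3, shot_noise = FALSE,
                     read_noise_sd = 0, background_level = 0, tube_glow = 0,
                     base_photon_rate = 0)
  st0 <- render_stack(cfg0)
  fr <- st0$frames[[1]]
  for (k in 1:3) {
    mp <- round(st0$geometry$marker_points[k, ])
    fr[(mp[2] - 8):(mp[2] + 8), (mp[1] - 8):(mp[1] + 8)] <- 0L
  }
  expect_true(all(fr == 0L))
})

test_that("rendered stacks are seed-deterministic", {
  cfg <- sim_config(n_days = 1 / 96, n_columns = 2, n_rows = 1,
                    image_size = c(160, 280), seed = 5)
  expect_identical(render_stack(cfg)$frames, render_stack(cfg)$frames)
})

test_that("a requested rotation moves the markers as constructed", {
  cfg <- sim_config(n_days = 1 / 288, n_columns = 2, n_rows = 1,
                    image_size = c(160, 280), seed = 2, rotation_deg = 5,
                    shot_noise = FALSE, read_noise_sd = 0)
  st <- render_stack(cfg)
  expected <- rotate_points(sim_layout(cfg)$marker_points, 5, cfg$image_size)
  expect_equal(unname(st$geometry$marker_points), unname(expected),
               tolerance = 1e-8)
  # markers refine to within half a pixel of the rotated truth
  ref <- align_tray(st$frames[[1]], st$geometry$marker_points)
  expect_lt(max(abs(ref$marker_points - expected)), 0.5)
})

test_that("saturating photon rates raise a warning and a flag", {
  cfg <- sim_config(n_days = 1 / 288, n_columns = 2, n_rows = 1,
                    image_size = c(160, 280), seed = 3, shot_noise = FALSE,
                    base_photon_rate = 1e4, rest_mean_min = 1e6,
                    act_mean_min = 1e-9)
  expect_warning(st <- render_stack(cfg), "16-bit")
  expect_true(st$saturated)
})

test_that("stacks round-trip through TIFF plus JSON sidecar", {
  st <- resting_stack()
  tif <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, tif)
  rt <- read_stack(tif)
  expect_identical(rt$frames, st$frames)
  expect_equal(rt$t_h, st$t_h)
  expect_equal(rt$geometry$tubes, st$geometry$tubes)
  expect_equal(rt$truth$flies[[1]]$true_period_h, 24)
  expect_equal(nrow(rt$truth$flies[[2]]$frames), length(st$frames))
})
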
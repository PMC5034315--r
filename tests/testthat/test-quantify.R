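test_that("contrast stretch is monotone, affine-invariant and range-filling", {
  set.seed(4)
  # sparse scene: dark background with a handful of bright pixels
  fr <- matrix(0, 80, 80)
  fr[sample(6400, 20)] <- runif(20, 1000, 65535)
  enh <- enhance_contrast(fr)
  expect_gte(min(enh), 0)
  expect_lte(max(enh), 65535)
  # ranking of pixel values is preserved
  o <- order(fr)
  expect_true(all(diff(enh[o]) >= 0))

  # positive affine transforms of the input give identical output
  enh2 <- enhance_contrast(3.7 * fr + 123)
  expect_equal(enh2, enh, tolerance = 1e-10)

  # a scene already spanning the full range, dark at the median, survives
  fr2 <- matrix(0, 80, 80)
  fr2[c(1, 5000)] <- c(65535, 30000)
  expect_equal(max(enhance_contrast(fr2)), 65535)
  expect_equal(enhance_contrast(fr2)[1, 1], 65535)

  cst <- enhance_contrast(matrix(5, 10, 10))
  expect_true(isTRUE(attr(cst, "constant")))
  expect_equal(unclass(cst)[1, 1], 5)
})

test_that("tube profiles have 46 bins with the right sums and maxima", {
  st <- small_stack()
  geom <- st$geometry
  v <- 2.5
  uni <- matrix(v, st$image_size[2], st$image_size[1])
  p <- profile_tube(uni, geom, 1, local_bg = 0)
  expect_length(p$bin_sum, 46)
  expect_true(all(p$bin_sum == 17 * 4 * v))
  expect_equal(p$tube_sd, 0)

  # single bright pixel lands in exactly one bin's maximum
  tb <- geom$tubes[1, ]
  one <- matrix(0, st$image_size[2], st$image_size[1])
  one[tb$y_min + 22, tb$x_min + 3] <- 99   # bin 6 (rows 21..24 of the tube)
  p1 <- profile_tube(one, geom, 1, local_bg = 0)
  expect_equal(which(p1$bin_max == 99), 6)
  expect_equal(sum(p1$bin_max == 99), 1)

  bad <- geom
  bad$tubes$y_max[1] <- bad$tubes$y_max[1] - 8L
  expect_error(profile_tube(uni, bad, 1, local_bg = 0), "spans")
})

test_that("the resting-peak rule flags, merges and anchors runs", {
  flat <- make_profile(rep(10, 46), rep(10, 46))
  expect_equal(nrow(detect_rest_peaks(flat)), 0)

  one <- rep(10, 46); one_max <- rep(3, 46); one_max[20] <- 500
  pk <- detect_rest_peaks(make_profile(one, one_max))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start_bin, 20L)
  expect_equal(pk$anchor_bin, 20)

  two_max <- rep(3, 46); two_max[c(12, 14)] <- 500
  pk2 <- detect_rest_peaks(make_profile(one, two_max))
  expect_equal(nrow(pk2), 2)

  adj_max <- rep(3, 46); adj_max[c(12, 13)] <- 500
  sums <- rep(10, 46); sums[12] <- 30; sums[13] <- 10
  pk3 <- detect_rest_peaks(make_profile(sums, adj_max))
  expect_equal(nrow(pk3), 1)
  expect_equal(pk3$start_bin, 12L)
  expect_equal(pk3$end_bin, 13L)
  # intensity-weighted centroid of the merged run
  expect_equal(pk3$anchor_bin, (12 * 30 + 13 * 10) / 40)
})

test_that("frame-time partition splits 300 s proportionally", {
  frame_s <- 300
  no_peaks <- partition_frame_time(make_profile(rep(5, 46)),
                                   detect_rest_peaks(make_profile(rep(5, 46))),
                                   frame_s)
  expect_equal(no_peaks$time_active_s, 300)
  expect_equal(no_peaks$time_rest_s, 0)
  expect_equal(no_peaks$quality, "ok")

  # everything in one peak, zero elsewhere: full rest
  sums <- rep(0, 46); sums[10] <- 4000
  pk <- tibble::tibble(start_bin = 10L, end_bin = 10L, anchor_bin = 10,
                       area = 4000)
  full_rest <- partition_frame_time(make_profile(sums), pk, frame_s)
  expect_equal(full_rest$time_rest_s, 300)

  # constructed equality of active and rest areas: 150 s each
  # mean_without_peaks over 45 non-peak bins = 2, A_active = 2 * 46 = 92;
  # peak bin holds 92 + 2 above that mean
  sums2 <- rep(2, 46); sums2[10] <- 94
  eq <- partition_frame_time(make_profile(sums2), pk, frame_s)
  expect_equal(eq$time_active_s, 150)
  expect_equal(eq$time_rest_s, 150)

  neg <- partition_frame_time(make_profile(rep(-1, 46)),
                              detect_rest_peaks(make_profile(rep(10, 46))),
                              frame_s)
  expect_equal(neg$quality, "negative_mean")
  expect_true(is.na(neg$time_active_s))

  dim <- partition_frame_time(make_profile(rep(0, 46)),
                              detect_rest_peaks(make_profile(rep(10, 46))),
                              frame_s)
  expect_equal(dim$quality, "too_dim")
})

test_that("every ok frame conserves exposure time exactly", {
  q <- small_quantified()
  ok <- q[q$quality == "ok", ]
  expect_gt(nrow(ok), 0)
  expect_true(all(abs(ok$time_active_s + ok$time_rest_s - 300) < 1e-9))
  expect_true(all(ok$time_active_s >= 0 & ok$time_rest_s >= 0))
})

test_that("bioluminescence sums the background-adjusted tube", {
  st <- small_stack()
  geom <- st$geometry
  zero <- matrix(0, st$image_size[2], st$image_size[1])
  expect_equal(tube_bioluminescence(zero, geom, 1), 0)

  # adding a constant to the tube and its background rectangle cancels
  fr <- matrix(rnorm(prod(st$image_size), 50, 2), st$image_size[2])
  tb <- geom$tubes[1, ]
  fr2 <- fr
  fr2[tb$y_min:tb$y_max, tb$x_min:tb$x_max] <-
    fr2[tb$y_min:tb$y_max, tb$x_min:tb$x_max] + 17
  fr2[tb$bg_y_min:tb$bg_y_max, tb$bg_x_min:tb$bg_x_max] <-
    fr2[tb$bg_y_min:tb$bg_y_max, tb$bg_x_min:tb$bg_x_max] + 17
  expect_equal(tube_bioluminescence(fr2, geom, 1),
               tube_bioluminescence(fr, geom, 1), tolerance = 1e-8)

  # a noise-free resting fly integrates to rate x 300 within 1%
  rst <- resting_stack()
  rate <- rst$truth$clock[[1]]$photon_rate[1]
  expect_equal(tube_bioluminescence(rst$frames[[1]], rst$geometry, 1),
               rate * 300, tolerance = 0.01)
})

test_that("bad frames interpolate linearly between good neighbours", {
  expect_equal(interpolate_series(c(100, NA, 200), c(FALSE, TRUE, FALSE)),
               c(100, 150, 200))
  x <- c(0, 1, 2, 3, 400)
  expect_equal(interpolate_series(x, c(FALSE, TRUE, TRUE, TRUE, FALSE)),
               c(0, 100, 200, 300, 400))
  expect_equal(interpolate_series(x, rep(FALSE, 5)), x)
  expect_error(interpolate_series(x, rep(TRUE, 5)), "all entries")

  parts <- make_partitions(rest_s = c(100, 0, 200), n_peaks = c(1L, 0L, 1L),
                           anchor = c(5, NA, 5))
  parts$quality <- c("ok", "negative_mean", "ok")
  parts$time_active_s <- c(200, NA, 100)
  parts$time_rest_s <- c(100, NA, 200)
  parts$biolum <- c(1000, NA, 3000)
  fixed <- interpolate_bad_frames(parts)
  expect_equal(fixed$time_rest_s, c(100, 150, 200))
  expect_equal(fixed$biolum, c(1000, 2000, 3000))
  expect_equal(fixed$interpolated, c(FALSE, TRUE, FALSE))
  expect_true(all(abs(fixed$time_active_s + fixed$time_rest_s - 300) < 1e-9))

  all_bad <- parts
  all_bad$quality <- "too_dim"
  expect_error(interpolate_bad_frames(all_bad), "all frames")
})
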
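make_results <- function(rs_a, rs_b, per_a = NULL, per_b = NULL,
                         sig_a = "clock", sig_b = "locomotor") {
  n <- length(rs_a)
  dplyr::bind_rows(
    tibble::tibble(fly_id = seq_len(n), signal = sig_a, rs = rs_a,
                   period_h = per_a %||% rep(24, n),
                   rhythmic = rs_a > 1.5, n = 336),
    tibble::tibble(fly_id = seq_len(n), signal = sig_b, rs = rs_b,
                   period_h = per_b %||% rep(24, n),
                   rhythmic = rs_b > 1.5, n = 336))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("paired RS correlation matches the covariance-formula oracle", {
  set.seed(5)
  rs_a <- runif(10, 2, 8)
  rs_b <- rs_a + rnorm(10, 0, 0.5)
  out <- paired_rs_correlation(make_results(rs_a, rs_b), "clock", "locomotor")
  r_oracle <- sum((rs_a - mean(rs_a)) * (rs_b - mean(rs_b))) /
    (stats::sd(rs_a) * stats::sd(rs_b) * 9)
  expect_equal(out$pearson_r, r_oracle, tolerance = 1e-12)
  # exact t-transform p-value
  tt <- r_oracle * sqrt(8 / (1 - r_oracle^2))
  expect_equal(out$p_value, 2 * stats::pt(-abs(tt), 8), tolerance = 1e-12)

  ident <- paired_rs_correlation(make_results(rs_a, rs_a), "clock", "locomotor")
  expect_equal(ident$pearson_r, 1)

  flipped <- 2 * mean(rs_a) - rs_a + 4    # sign-flipped about the centre
  out2 <- paired_rs_correlation(make_results(rs_a, flipped), "clock", "locomotor")
  expect_equal(out2$pearson_r, -1)
})

test_that("only flies rhythmic on both signals enter paired statistics", {
  rs_a <- c(5, 5.5, 5, 1, 5.2)
  rs_b <- c(4, 4.5, 1, 4.2, 4.8)
  out <- paired_rs_correlation(make_results(rs_a, rs_b), "clock", "locomotor")
  expect_equal(out$n, 3L)

  few <- paired_rs_correlation(make_results(c(5, 1, 1, 1), c(4, 4, 4, 4)),
                               "clock", "locomotor")
  expect_true(is.na(few$pearson_r))
  expect_match(few$note, "fewer than 3")
})

test_that("paired period tests report correlation and mean difference", {
  per <- c(23.1, 23.8, 24.4, 25, 23.5, 24.9)
  same <- paired_period_correlation(
    make_results(rep(5, 6), rep(5, 6), per, per), "clock", "locomotor")
  expect_equal(same$pearson_r, 1)
  expect_equal(same$t_stat, 0)          # identical periods: no difference
  expect_equal(same$t_p_value, 1)
  expect_equal(same$mean_diff_h, 0)

  jitter <- c(0.3, 0.6, 0.4, 0.7, 0.5, 0.4)
  shifted <- paired_period_correlation(
    make_results(rep(5, 6), rep(5, 6), per + jitter, per), "clock", "locomotor")
  expect_equal(shifted$mean_diff_h, mean(jitter), tolerance = 1e-12)
  tt <- stats::t.test(per + jitter, per, paired = TRUE)
  expect_equal(shifted$t_stat, unname(tt$statistic))
  expect_equal(shifted$t_p_value, tt$p.value)
})

test_that("percent rhythmic is a simple threshold count", {
  res <- make_results(c(5, 5, 5, 5, 5, 5, 1, 1, 1, 1), rep(5, 10))
  expect_equal(percent_rhythmic(res, "clock"), 60)
  expect_equal(percent_rhythmic(res, "locomotor"), 100)
  expect_equal(percent_rhythmic(make_results(rep(0.2, 4), rep(1, 4)), "clock"), 0)
  expect_error(percent_rhythmic(res, "humidity"), "no flies")
})

test_that("time-partition fractions sum to one and compare across cohorts", {
  p <- make_partitions(rest_s = c(300, 300, 100, 0, 250, 250),
                       n_peaks = c(1L, 1L, 0L, 0L, 1L, 1L),
                       anchor = c(7, 7, NA, NA, 20, 20))
  s <- assign_sleep_episodes(p)
  fr <- partition_fractions(s)
  expect_equal(fr$sleep_frac + fr$rest_frac + fr$active_frac, 1,
               tolerance = 1e-9)
  expect_equal(fr$sleep_frac, 1100 / 1800)
  expect_equal(fr$rest_frac, 100 / 1800)

  # identical cohorts produce a zero chi-square statistic
  two <- dplyr::bind_rows(dplyr::mutate(fr, cohort = "a"),
                          dplyr::mutate(fr, cohort = "b"))
  cmp <- partition_comparison(two)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)

  # hand-built 2 x 3 table reproduces the textbook statistic
  counts <- rbind(c(120, 40, 140), c(100, 60, 140))
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat_oracle <- sum((counts - expected)^2 / expected)
  fr2 <- tibble::tibble(
    fly_id = 1:2, cohort = c("a", "b"),
    sleep_frac = counts[, 1] / rowSums(counts),
    rest_frac = counts[, 2] / rowSums(counts),
    active_frac = counts[, 3] / rowSums(counts),
    total_s = rowSums(counts) * 300)
  cmp2 <- partition_comparison(fr2)
  expect_equal(cmp2$statistic, stat_oracle, tolerance = 1e-9)
  expect_error(partition_comparison(dplyr::mutate(fr, cohort = "only")),
               "2 cohorts")
})

test_that("population traces average flies with a sampling-consistent SEM", {
  b <- dplyr::bind_rows(
    tibble::tibble(fly_id = 1, t_h = c(0.25, 0.75), biolum = c(10, 10)),
    tibble::tibble(fly_id = 2, t_h = c(0.25, 0.75), biolum = c(20, 20)))
  tr <- population_mean_trace(b)
  expect_equal(tr$mean, c(15, 15))
  expect_equal(tr$sem, rep(stats::sd(c(10, 20)) / sqrt(2), 2))

  one <- population_mean_trace(b[b$fly_id == 1, ])
  expect_equal(one$mean, c(10, 10))
  expect_true(all(is.na(one$sem)))

  # for iid noise the SEM tracks sd/sqrt(n)
  set.seed(8)
  n_fly <- 40
  noise <- dplyr::bind_rows(lapply(seq_len(n_fly), function(i)
    tibble::tibble(fly_id = i, t_h = seq(0.25, 12, by = 0.5),
                   biolum = rnorm(24))))
  trn <- population_mean_trace(noise)
  expect_equal(mean(trn$sem), 1 / sqrt(n_fly), tolerance = 0.15)

  ragged <- dplyr::bind_rows(noise, tibble::tibble(
    fly_id = n_fly + 1, t_h = 0.25, biolum = 0))
  expect_error(population_mean_trace(ragged), "lengths")

  expect_s3_class(plot_population_trace(trn), "ggplot")
})

test_that("fly trace plots assemble the three signals", {
  cfg <- sim_config(n_days = 2, n_columns = 3, n_rows = 1,
                    image_size = c(200, 280), seed = 12)
  b <- simulate_fly_series(cfg, 1)
  expect_s3_class(plot_fly_traces(b), "ggplot")
})
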
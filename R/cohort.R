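#' Percentage of rhythmic flies for one signal
#'
#' @param results Tibble from [analyze_cohort()].
#' @param signal Signal name (`"clock"`, `"locomotor"`,
#'   `"sleep_consolidation"`).
#' @param rs_threshold Rhythmicity cutoff.
#' @return Percentage of flies with RS above the threshold.
#' @export
percent_rhythmic <- function(results, signal, rs_threshold = 1.5) {
  rs <- results$rs[results$signal == signal]
  if (!length(rs)) stop("no flies with signal ", signal, call. = FALSE)
  100 * mean(rs > rs_threshold)
}

pair_signals <- function(results, signal_a, signal_b, rs_threshold = 1.5) {
  a <- results[results$signal == signal_a, c("fly_id", "rs", "period_h")]
  b <- results[results$signal == signal_b, c("fly_id", "rs", "period_h")]
  m <- dplyr::inner_join(a, b, by = "fly_id", suffix = c("_a", "_b"))
  m[m$rs_a > rs_threshold & m$rs_b > rs_threshold, ]
}

#' Paired RS correlation between two signals
#'
#' Single-fly coupling analysis: flies rhythmic (RS above threshold) on
#' both signals contribute their paired RS values to a Pearson
#' correlation; a significant correlation indicates that the two
#' rhythm generators are coupled. The p-value is the exact two-sided
#' t-transform of r.
#'
#' @param results Tibble from [analyze_cohort()].
#' @param signal_a,signal_b Signal names.
#' @param rs_threshold Rhythmicity cutoff for inclusion.
#' @return One-row tibble: `pair`, `n`, `pearson_r`, `p_value`, `note`
#'   (`NA` unless the result is undefined, e.g. fewer than 3 qualifying
#'   flies).
#' @export
paired_rs_correlation <- function(results, signal_a, signal_b,
                                  rs_threshold = 1.5) {
  m <- pair_signals(results, signal_a, signal_b, rs_threshold)
  pair <- paste0("RS-", signal_a, " vs RS-", signal_b)
  if (nrow(m) < 3)
    return(tibble::tibble(pair = pair, n = nrow(m), pearson_r = NA_real_,
                          p_value = NA_real_,
                          note = "fewer than 3 flies rhythmic for both signals"))
  ct <- stats::cor.test(m$rs_a, m$rs_b, method = "pearson")
  tibble::tibble(pair = pair, n = nrow(m), pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, note = NA_character_)
}

#' Paired period correlation and paired t-test between two signals
#'
#' Among flies rhythmic on both signals with a defined period for each,
#' computes the Pearson correlation of the paired periods (shared
#' period-setting machinery shows up as covariance) and a two-sided
#' paired t-test on the per-fly period difference (signal_a minus
#' signal_b).
#'
#' @inheritParams paired_rs_correlation
#' @return One-row tibble: `pair`, `n`, `pearson_r`, `p_value`,
#'   `mean_diff_h`, `t_stat`, `t_p_value`, `note`.
#' @export
paired_period_correlation <- function(results, signal_a, signal_b,
                                      rs_threshold = 1.5) {
  m <- pair_signals(results, signal_a, signal_b, rs_threshold)
  m <- m[!is.na(m$period_h_a) & !is.na(m$period_h_b), ]
  pair <- paste0("period-", signal_a, " vs period-", signal_b)
  if (nrow(m) < 3)
    return(tibble::tibble(pair = pair, n = nrow(m), pearson_r = NA_real_,
                          p_value = NA_real_, mean_diff_h = NA_real_,
                          t_stat = NA_real_, t_p_value = NA_real_,
                          note = "fewer than 3 flies rhythmic for both signals"))
  ct <- stats::cor.test(m$period_h_a, m$period_h_b, method = "pearson")
  d <- m$period_h_a - m$period_h_b
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    # degenerate paired t-test: constant difference
    t_stat <- if (abs(mean(d)) < .Machine$double.eps^0.5) 0 else sign(mean(d)) * Inf
    t_p <- if (t_stat == 0) 1 else 0
  } else {
    tt <- stats::t.test(d)
    t_stat <- unname(tt$statistic)
    t_p <- tt$p.value
  }
  tibble::tibble(pair = pair, n = nrow(m), pearson_r = unname(ct$estimate),
                 p_value = ct$p.value,
                 mean_diff_h = mean(d), t_stat = t_stat,
                 t_p_value = t_p, note = NA_character_)
}

#' Per-fly partition of recording time into sleep, rest and activity
#'
#' Sleep is immobility in qualifying episodes; rest is immobility that
#' does not qualify (shorter than the five-minute threshold); activity
#' is the remainder. Computed frame-wise: a sleep frame's rest seconds
#' count as sleep, a non-sleep frame's rest seconds as rest, and
#' active seconds always as activity. Fractions sum to 1 per fly.
#'
#' @param sleep_df Tibble from [assign_sleep_episodes()].
#' @return Tibble: `fly_id`, `sleep_frac`, `rest_frac`, `active_frac`,
#'   `total_s`.
#' @export
partition_fractions <- function(sleep_df) {
  dplyr::summarise(
    dplyr::group_by(sleep_df, .data$fly_id),
    sleep_s = sum(.data$time_rest_s * (.data$sleep_binary == 1), na.rm = TRUE),
    rest_s = sum(.data$time_rest_s * (.data$sleep_binary == 0), na.rm = TRUE),
    active_s = sum(.data$time_active_s, na.rm = TRUE),
    total_s = .data$sleep_s + .data$rest_s + .data$active_s,
    sleep_frac = .data$sleep_s / .data$total_s,
    rest_frac = .data$rest_s / .data$total_s,
    active_frac = .data$active_s / .data$total_s,
    .groups = "drop")[, c("fly_id", "sleep_frac", "rest_frac",
                          "active_frac", "total_s")]
}

#' Compare time partitioning across cohorts
#'
#' Mean sleep/rest/active fractions per cohort, plus a chi-square test
#' on the pooled 3-category partition. The contingency table counts
#' 300-s frame-equivalents per category so the test operates on event
#' counts rather than raw seconds.
#'
#' @param fractions Tibble from [partition_fractions()] with an added
#'   `cohort` column.
#' @param frame_s Seconds per frame-equivalent.
#' @return List of class `partition_comparison`: `means` (tibble),
#'   `counts` (cohort x category matrix), `statistic`, `df`, `p_value`.
#' @export
partition_comparison <- function(fractions, frame_s = 300) {
  if (!"cohort" %in% names(fractions))
    stop("`fractions` needs a `cohort` column", call. = FALSE)
  if (length(unique(fractions$cohort)) < 2)
    stop("need at least 2 cohorts to compare", call. = FALSE)
  if (any(!table(fractions$cohort)))
    stop("empty cohort", call. = FALSE)
  means <- dplyr::summarise(
    dplyr::group_by(fractions, .data$cohort),
    n = dplyr::n(),
    sleep_frac = mean(.data$sleep_frac),
    rest_frac = mean(.data$rest_frac),
    active_frac = mean(.data$active_frac),
    .groups = "drop")
  secs <- dplyr::summarise(
    dplyr::group_by(fractions, .data$cohort),
    sleep = sum(.data$sleep_frac * .data$total_s),
    rest = sum(.data$rest_frac * .data$total_s),
    active = sum(.data$active_frac * .data$total_s),
    .groups = "drop")
  counts <- round(as.matrix(secs[, c("sleep", "rest", "active")]) / frame_s)
  rownames(counts) <- as.character(secs$cohort)
  tab <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  ch <- suppressWarnings(stats::chisq.test(tab))
  structure(list(means = means, counts = counts,
                 statistic = unname(ch$statistic),
                 df = unname(ch$parameter), p_value = ch$p.value),
            class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat(sprintf("<partition_comparison> chi-square = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  print(x$means)
  invisible(x)
}

#' Population mean trace with SEM
#'
#' Per-timepoint mean and standard error across flies for one binned
#' signal.
#'
#' @param binned Tibble from [bin_fly_series()].
#' @param value Column to average (default `biolum`).
#' @return Tibble: `t_h`, `mean`, `sem` (`NA` for a single fly), `n`.
#' @export
population_mean_trace <- function(binned, value = "biolum") {
  if (!value %in% names(binned))
    stop("no column ", value, " in binned series", call. = FALSE)
  lens <- table(binned$fly_id)
  if (length(unique(lens)) != 1)
    stop("flies have binned series of different lengths", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(binned, .data$t_h),
    mean = mean(.data[[value]]),
    sem = if (dplyr::n() > 1) stats::sd(.data[[value]]) / sqrt(dplyr::n())
          else NA_real_,
    n = dplyr::n(),
    .groups = "drop")
}
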
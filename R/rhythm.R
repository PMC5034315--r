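#' Butterworth low-pass detrending by trend division
#'
#' The slow trend (periods longer than `cutoff_period_h`, by default
#' 72 h -- chiefly the exponential decay of the luciferin substrate) is
#' extracted with a zero-phase order-2 Butterworth low-pass filter
#' (forward-backward filtering over a reflection-padded copy of the
#' series), and the series is divided pointwise by it. Division, rather
#' than subtraction, removes the measurement units and preserves the
#' relative amplitude of the oscillation around the trend; the result
#' is renormalised by its own mean so the detrended series has mean
#' exactly 1.
#'
#' @param series Numeric vector sampled at `bin_h`-hour intervals, at
#'   least 2 days long; its trend must stay strictly positive.
#' @param cutoff_period_h Filter cutoff as a period, hours.
#' @param bin_h Sampling interval, hours.
#' @param order Butterworth order.
#' @return Numeric vector of unitless ratios with mean 1 (to within
#'   1e-6); the extracted trend is attached as attribute `"trend"`.
#' @export
#' @examples
#' t <- seq(0, 167.5, by = 0.5)
#' x <- 100 * 2^(-t / 70) * (1 + 0.3 * cos(2 * pi * t / 24))
#' d <- butterworth_detrend(x)
#' mean(d)
butterworth_detrend <- function(series, cutoff_period_h = 72, bin_h = 0.5,
                                order = 2) {
  n <- length(series)
  if (n * bin_h < 48)
    stop("need at least 2 days of data to detrend", call. = FALSE)
  if (anyNA(series)) stop("series contains NA", call. = FALSE)
  nyquist <- 1 / (2 * bin_h)                       # cycles per hour
  bf <- signal::butter(order, (1 / cutoff_period_h) / nyquist, type = "low")
  pad <- n
  centred <- series - mean(series)
  padded <- c(rev(centred[seq_len(pad)]), centred, rev(centred)[seq_len(pad)])
  trend <- mean(series) + signal::filtfilt(bf, padded)[pad + seq_len(n)]
  if (any(trend <= 0)) {
    bad <- which(trend <= 0)[1]
    stop(sprintf("trend is non-positive at sample %d (t = %g h)",
                 bad, (bad - 1) * bin_h), call. = FALSE)
  }
  out <- series / trend
  out <- out / mean(out)
  attr(out, "trend") <- trend
  out
}

#' Autocorrelation correlogram of a detrended series
#'
#' Mean-removed sample autocorrelation (biased, divide-by-n estimator,
#' as returned by [stats::acf()]) over lags 0 to n/2, normalised so the
#' zero-lag value is 1.
#'
#' @param series Numeric vector with positive variance.
#' @param bin_h Sampling interval, hours.
#' @return Tibble with `lag` (samples), `lag_h` (hours) and `acf`;
#'   attributes `n` and `bin_h`.
#' @export
correlogram <- function(series, bin_h = 0.5) {
  series <- as.numeric(series)
  if (anyNA(series)) stop("series contains NA", call. = FALSE)
  if (stats::var(series) <= 0)
    stop("series has zero variance; correlogram undefined", call. = FALSE)
  n <- length(series)
  a <- stats::acf(series, lag.max = floor(n / 2), plot = FALSE, demean = TRUE)
  out <- tibble::tibble(lag = as.integer(a$lag[, 1, 1]),
                        lag_h = a$lag[, 1, 1] * bin_h,
                        acf = a$acf[, 1, 1])
  attr(out, "n") <- n
  attr(out, "bin_h") <- bin_h
  out
}

# highest positive local maximum of the ACF in the circadian lag window
circadian_peak <- function(cg, window_h = c(14, 38)) {
  bin_h <- attr(cg, "bin_h") %||% (cg$lag_h[2] - cg$lag_h[1])
  in_win <- cg$lag_h >= window_h[1] & cg$lag_h <= window_h[2]
  if (!any(in_win)) stop("circadian lag window is empty", call. = FALSE)
  k <- which(in_win)
  interior <- k[k > 1 & k < nrow(cg)]
  v <- cg$acf
  is_max <- v[interior] > v[interior - 1] & v[interior] >= v[interior + 1] &
    v[interior] > 0
  cand <- interior[is_max]
  if (!length(cand)) return(NULL)
  best <- cand[which.max(v[cand])]
  list(index = best, lag = cg$lag[best], height = v[best], bin_h = bin_h)
}

#' Rhythmicity statistic (RS)
#'
#' The height of the circadian correlogram peak -- the highest positive
#' local maximum of the autocorrelation at lags between 14 and 38 h --
#' divided by the 95% confidence line for a white-noise autocorrelation,
#' `2/sqrt(n)`. A series with no positive correlogram peak in the window
#' scores 0. Values above 1.5 define rhythmicity.
#'
#' @param cg Correlogram tibble from [correlogram()].
#' @param n Number of samples in the series (taken from the correlogram
#'   attribute when omitted).
#' @param window_h Circadian lag window, hours.
#' @return Scalar RS value.
#' @export
rhythmicity_statistic <- function(cg, n = attr(cg, "n"), window_h = c(14, 38)) {
  if (is.null(n)) stop("sample count `n` unknown", call. = FALSE)
  if (n < 96)
    stop("need at least 2 days of 30-min samples (n >= 96) for RS", call. = FALSE)
  pk <- circadian_peak(cg, window_h)
  if (is.null(pk)) return(0)
  pk$height / (2 / sqrt(n))
}

#' Circadian period from the correlogram peak
#'
#' Lag of the circadian correlogram peak, refined by three-point
#' parabolic interpolation around the maximum and converted to hours.
#' `NA` when no qualifying peak exists (an arrhythmic series has no
#' defined period; this is not an error).
#'
#' @inheritParams rhythmicity_statistic
#' @return Period in hours, or `NA_real_`.
#' @export
estimate_period <- function(cg, window_h = c(14, 38)) {
  pk <- circadian_peak(cg, window_h)
  if (is.null(pk)) return(NA_real_)
  i <- pk$index
  if (i > 1 && i < nrow(cg)) {
    y0 <- cg$acf[i - 1]; y1 <- cg$acf[i]; y2 <- cg$acf[i + 1]
    denom <- y0 - 2 * y1 + y2
    shift <- if (abs(denom) > .Machine$double.eps) 0.5 * (y0 - y2) / denom else 0
    shift <- max(min(shift, 0.5), -0.5)
  } else shift <- 0
  (cg$lag[i] + shift) * pk$bin_h
}

#' Fit the rhythmicity analysis to one binned series
#'
#' Convenience wrapper chaining detrending, the correlogram, the
#' rhythmicity statistic and period estimation into a single fitted
#' object with [generics::tidy()], [generics::glance()] and
#' `autoplot()` methods.
#'
#' @param series Numeric 30-min-binned series.
#' @param bin_h Sampling interval, hours.
#' @param detrend `"divide"` (Butterworth trend division, the standard
#'   treatment for decaying bioluminescence), `"mean"` (divide by the
#'   series mean only; the autocorrelation is scale-invariant so this
#'   simply skips trend removal) or `"none"`.
#' @param cutoff_period_h Detrend filter cutoff, hours.
#' @param window_h Circadian lag window for the RS peak.
#' @param rs_threshold RS value above which a series is called rhythmic.
#' @param signal_kind Optional label (`"clock"`, `"locomotor"`,
#'   `"sleep_consolidation"`, ...).
#' @return Object of class `rhythm_fit`.
#' @export
fit_rhythm <- function(series, bin_h = 0.5,
                       detrend = c("divide", "mean", "none"),
                       cutoff_period_h = 72, window_h = c(14, 38),
                       rs_threshold = 1.5, signal_kind = NA_character_) {
  detrend <- match.arg(detrend)
  detrended <- switch(detrend,
    divide = butterworth_detrend(series, cutoff_period_h, bin_h),
    mean = if (mean(series) != 0) series / mean(series) else series,
    none = series)
  cg <- correlogram(as.numeric(detrended), bin_h)
  rs <- rhythmicity_statistic(cg, window_h = window_h)
  period <- if (rs > 0) estimate_period(cg, window_h) else NA_real_
  structure(
    list(series = as.numeric(series), detrended = as.numeric(detrended),
         trend = attr(detrended, "trend"), correlogram = cg,
         rs = rs, period_h = period, rhythmic = rs > rs_threshold,
         n = length(series), bin_h = bin_h, window_h = window_h,
         detrend = detrend, rs_threshold = rs_threshold,
         signal_kind = signal_kind),
    class = "rhythm_fit"
  )
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat(sprintf("<rhythm_fit%s> n = %d, RS = %.2f (%s), period = %s h\n",
              if (is.na(x$signal_kind)) "" else paste0(": ", x$signal_kind),
              x$n, x$rs, if (x$rhythmic) "rhythmic" else "not rhythmic",
              if (is.na(x$period_h)) "undefined" else sprintf("%.2f", x$period_h)))
  invisible(x)
}

#' Analyse the three signals of one fly
#'
#' Runs the rhythm analysis on the clock (bioluminescence), locomotor
#' (percent time active) and sleep-consolidation series of a single
#' fly's 30-min-binned data. Every signal is Butterworth-detrended by
#' trend division; a behavioural series whose low-pass trend touches
#' zero (e.g. an arrhythmic fly that stops sleeping) falls back to
#' plain mean normalisation, which leaves its autocorrelation unchanged.
#'
#' @param binned One fly's tibble from [bin_fly_series()].
#' @param bin_h Sampling interval, hours.
#' @param ... Passed to [fit_rhythm()].
#' @return Tibble with one row per signal: `signal`, `rs`, `period_h`,
#'   `rhythmic`, `n`.
#' @export
analyze_fly <- function(binned, bin_h = 0.5, ...) {
  signals <- c(clock = "biolum", locomotor = "pct_active",
               sleep_consolidation = "consolidation_min")
  miss <- setdiff(unname(signals), names(binned))
  if (length(miss))
    stop("binned series lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lens <- vapply(signals, function(cl) sum(!is.na(binned[[cl]])), integer(1))
  if (length(unique(lens)) != 1)
    stop("signal series have mismatched lengths", call. = FALSE)
  purrr::imap_dfr(signals, function(col, kind) {
    x <- binned[[col]]
    fit <- tryCatch(
      fit_rhythm(x, bin_h = bin_h, detrend = "divide", signal_kind = kind, ...),
      error = function(e)
        fit_rhythm(x, bin_h = bin_h, detrend = "mean", signal_kind = kind, ...))
    tibble::tibble(signal = kind, rs = fit$rs, period_h = fit$period_h,
                   rhythmic = fit$rhythmic, n = fit$n)
  })
}

#' Analyse every fly of a cohort
#'
#' @param binned Tibble from [bin_fly_series()] with a `fly_id` column.
#' @param ... Passed to [analyze_fly()].
#' @return Tibble: `fly_id`, `signal`, `rs`, `period_h`, `rhythmic`, `n`.
#' @export
analyze_cohort <- function(binned, ...) {
  grp <- factor(binned$fly_id, levels = unique(binned$fly_id))
  dplyr::bind_rows(lapply(split(binned, grp), function(df)
    dplyr::mutate(analyze_fly(df, ...), fly_id = df$fly_id[1], .before = 1)))
}
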
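#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a rhythm fit into its correlogram
#'
#' @param x A `rhythm_fit`.
#' @param ... Unused.
#' @return Tibble with `lag`, `lag_h`, `acf` and an `in_window` flag for
#'   the circadian peak-search window.
#' @method tidy rhythm_fit
#' @export
tidy.rhythm_fit <- function(x, ...) {
  cg <- x$correlogram
  cg$in_window <- cg$lag_h >= x$window_h[1] & cg$lag_h <= x$window_h[2]
  cg
}

#' One-row summary of a rhythm fit
#'
#' @param x A `rhythm_fit`.
#' @param ... Unused.
#' @return Tibble: `signal`, `rs`, `period_h`, `rhythmic`, `n`, `bin_h`.
#' @method glance rhythm_fit
#' @export
glance.rhythm_fit <- function(x, ...) {
  tibble::tibble(signal = x$signal_kind, rs = x$rs, period_h = x$period_h,
                 rhythmic = x$rhythmic, n = x$n, bin_h = x$bin_h)
}

#' Correlogram plot of a rhythm fit
#'
#' Autocorrelation against lag with the circadian search window shaded,
#' the 95% white-noise line at 2/sqrt(n), the rhythmicity threshold at
#' `rs_threshold` times that line, and the detected peak marked.
#'
#' @param object A `rhythm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rhythm_fit
#' @export
autoplot.rhythm_fit <- function(object, ...) {
  cg <- tidy(object)
  ci <- 2 / sqrt(object$n)
  p <- ggplot2::ggplot(cg, ggplot2::aes(x = .data$lag_h, y = .data$acf)) +
    ggplot2::annotate("rect", xmin = object$window_h[1], xmax = object$window_h[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_hline(yintercept = c(ci, object$rs_threshold * ci),
                        linetype = c("dashed", "dotted"), colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Lag (h)", y = "Autocorrelation",
                  subtitle = sprintf("RS = %.2f%s", object$rs,
                                     if (is.na(object$period_h)) "" else
                                       sprintf(", period = %.2f h", object$period_h)))
  if (!is.na(object$period_h))
    p <- p + ggplot2::geom_vline(xintercept = object$period_h,
                                 colour = "firebrick", linetype = "dashed")
  p
}

#' Plot the three binned signals of one fly
#'
#' Molecular clock, locomotor activity and sleep consolidation stacked
#' on a shared circadian time axis, with subjective-night spans shaded
#' (recording starts at subjective dusk).
#'
#' @param binned One fly's tibble from [bin_fly_series()] or
#'   [simulate_fly_series()].
#' @param night_h Length of the subjective night at the start of each
#'   cycle, hours.
#' @param period_h Cycle length used for the shading, hours.
#' @return A ggplot.
#' @export
plot_fly_traces <- function(binned, night_h = 12, period_h = 24) {
  long <- tidyr::pivot_longer(
    binned[c("t_h", "biolum", "pct_active", "consolidation_min")],
    -"t_h", names_to = "signal", values_to = "value")
  long$signal <- factor(long$signal,
                        levels = c("biolum", "pct_active", "consolidation_min"),
                        labels = c("Molecular clock (counts)",
                                   "Locomotor activity (% time)",
                                   "Sleep consolidation (min)"))
  nights <- tibble::tibble(start = seq(0, max(binned$t_h), by = period_h))
  nights$end <- pmin(nights$start + night_h, max(binned$t_h))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_h, y = .data$value)) +
    ggplot2::geom_rect(data = nights, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = -Inf, ymax = Inf), alpha = 0.12) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Circadian time since recording start (h)", y = NULL)
}

#' Plot a population mean trace with its SEM ribbon
#'
#' @param trace Tibble from [population_mean_trace()].
#' @param ylab Y-axis label.
#' @return A ggplot.
#' @export
plot_population_trace <- function(trace, ylab = "Mean signal") {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$t_h, y = .data$mean))
  if (any(!is.na(trace$sem)))
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                               ymax = .data$mean + .data$sem),
                                  alpha = 0.25)
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Circadian time since recording start (h)", y = ylab)
}
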
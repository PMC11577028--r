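#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_ribbon
#'   geom_histogram labs facet_wrap scale_y_log10 theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a waveform
#'
#' @param object a `waveform`.
#' @param ... unused.
#' @return A ggplot oscillogram.
#' @export
autoplot.waveform <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(x = .data$time, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    labs(x = "Time (s)", y = "Velocity (mm/s)", title = wave_label(object)) +
    theme_minimal()
}

#' Plot a two-channel petiole pair
#'
#' @param object a `two_channel_waveform`.
#' @param ... unused.
#' @return A ggplot with one facet per channel.
#' @export
autoplot.two_channel_waveform <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("ipsi", "contra"),
                              names_to = "channel", values_to = "value")
  ggplot(long, aes(x = .data$time, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, ncol = 1) +
    labs(x = "Time (s)", y = "Velocity (mm/s)") +
    theme_minimal()
}

#' Plot an inter-event interval histogram
#'
#' @param object an `interval_histogram`.
#' @param ... unused.
#' @return A ggplot bar chart over interval bins.
#' @export
autoplot.interval_histogram <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(x = .data$bin_mid_ms, y = .data$count)) +
    geom_col(width = attr(object, "bin_ms")) +
    labs(x = "Inter-event interval (ms)", y = "Count") +
    theme_minimal()
}

#' Plot a delay distribution
#'
#' @param object a `delay_set`.
#' @param binwidth histogram bin width (ms).
#' @param ... unused.
#' @return A ggplot histogram of signed ipsi-contra delays.
#' @export
autoplot.delay_set <- function(object, binwidth = 0.5, ...) {
  ggplot(tibble::as_tibble(object), aes(x = .data$delay_ms)) +
    geom_histogram(binwidth = binwidth) +
    labs(x = "Delay, contra - ipsi (ms)", y = "Count") +
    theme_minimal()
}

#' Plot a kernel rate estimate (PSTH)
#'
#' @param object a `rate_estimate`.
#' @param ... unused.
#' @return A ggplot rate curve with an across-trial SD ribbon when available.
#' @export
autoplot.rate_estimate <- function(object, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot(d, aes(x = .data$t, y = .data$rate))
  if (!all(is.na(d$sd))) {
    p <- p + geom_ribbon(aes(ymin = pmax(.data$rate - .data$sd, 0),
                             ymax = .data$rate + .data$sd),
                         fill = "pink", alpha = 0.6)
  }
  p + geom_line(colour = "red") +
    labs(x = "Time (s)", y = "Rate (spikes/s)") +
    theme_minimal()
}

#' Plot a spike-train power spectrum
#'
#' @param object a `spectrum_estimate`.
#' @param f_max upper frequency limit of the plot (Hz).
#' @param ... unused.
#' @return A ggplot power-spectrum line (log power).
#' @export
autoplot.spectrum_estimate <- function(object, f_max = 500, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$f > 0, .data$f <= f_max)
  ggplot(d, aes(x = .data$f, y = .data$power)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "Frequency (Hz)", y = "Power (a.u.)") +
    theme_minimal()
}

#' Summary plot of one grid metric across conditions
#'
#' @param result a `result_table` from [run_grid()].
#' @param metric metric name to plot (see [run_grid()]).
#' @return A ggplot of metric vs SNR, coloured by band, faceted by
#'   threshold x preset. Control cells are drawn as horizontal references.
#' @export
plot_grid_metric <- function(result, metric = "interval_iqr_ms") {
  stopifnot(inherits(result, "result_table"))
  d <- dplyr::filter(tibble::as_tibble(result), .data$metric == !!metric)
  test <- dplyr::filter(d, .data$band != "none")
  ctrl <- dplyr::filter(d, .data$band == "none")
  p <- ggplot(test, aes(x = .data$snr_db, y = .data$value,
                        colour = .data$band)) +
    geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    facet_wrap(threshold ~ preset, scales = "free_y") +
    labs(x = "SNR (dB, decreasing = louder noise)", y = metric,
         colour = "Noise band") +
    theme_minimal()
  if (nrow(ctrl)) {
    p <- p + ggplot2::geom_hline(data = ctrl,
                                 aes(yintercept = .data$value),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
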
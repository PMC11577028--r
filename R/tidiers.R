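#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an event train
#'
#' @param x an `event_train`.
#' @param ... unused.
#' @return A plain tibble of events with onset, midpoint and channel.
#' @export
tidy.event_train <- function(x, ...) {
  tibble::tibble(
    channel = attr(x, "channel") %||% "",
    onset = x$onset,
    midpoint = x$midpoint
  )
}

#' One-row summary of an event train
#'
#' @param x an `event_train`.
#' @param ... unused.
#' @return Tibble with event count, interval summaries and model settings.
#' @export
glance.event_train <- function(x, ...) {
  iv <- if (nrow(x) > 1L) diff(x$midpoint) * 1000 else numeric()
  tibble::tibble(
    n_events = nrow(x),
    min_interval_ms = if (length(iv)) min(iv) else NA_real_,
    median_interval_ms = if (length(iv)) stats::median(iv) else NA_real_,
    threshold = attr(x, "threshold"),
    refractory = attr(x, "refractory"),
    duration = attr(x, "duration")
  )
}

#' Tidy a delay set
#'
#' @param x a `delay_set`.
#' @param ... unused.
#' @return A plain tibble of paired event times and signed delays.
#' @export
tidy.delay_set <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a delay set
#'
#' @param x a `delay_set`.
#' @param ... unused.
#' @return Tibble with pair count, unpaired count, and delay summaries.
#' @export
glance.delay_set <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_unpaired = attr(x, "n_unpaired"),
    median_delay_ms = if (nrow(x)) stats::median(x$delay_ms) else NA_real_,
    frac_positive = if (nrow(x)) mean(x$delay_ms > 0) else NA_real_
  )
}

#' One-row summary of a rate estimate
#'
#' @param x a `rate_estimate`.
#' @param ... unused.
#' @return Tibble with mean/peak rate and the implied spike count.
#' @export
glance.rate_estimate <- function(x, ...) {
  dt <- attr(x, "dt")
  tibble::tibble(
    mean_rate = mean(x$rate),
    peak_rate = max(x$rate),
    t_peak = x$t[which.max(x$rate)],
    spikes_per_trial = sum(x$rate) * dt,
    sigma = attr(x, "sigma"),
    n_trials = attr(x, "n_trials")
  )
}

#' One-row summary of a spectrum estimate
#'
#' @param x a `spectrum_estimate`.
#' @param ... unused.
#' @return Tibble with the non-DC peak frequency and its power.
#' @export
glance.spectrum_estimate <- function(x, ...) {
  f_pk <- peak_frequency(x)
  tibble::tibble(
    peak_f = f_pk,
    peak_power = x$power[match(f_pk, x$f)],
    resolution_hz = x$f[2] - x$f[1]
  )
}
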
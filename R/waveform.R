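#' Uniformly sampled waveform
#'
#' The universal signal carrier of the package: a tibble with columns `time`
#' (seconds) and `value` (substrate velocity, mm/s), carrying the sampling
#' rate and a free-text channel label as attributes. All stimulus synthesis,
#' transmission and event-detection functions consume and produce waveforms.
#'
#' @param samples numeric vector of velocity samples (mm/s); must be finite
#'   and of length >= 1.
#' @param rate sampling rate in Hz; must be > 0.
#' @param label free-text channel tag (e.g. `"fcs"`, `"ipsi"`).
#' @return A `waveform`: a tibble with columns `time` and `value` and
#'   attributes `rate` and `label`.
#' @examples
#' w <- waveform(sin(2 * pi * 89 * seq(0, 0.1, by = 1e-4)), rate = 1e4)
#' wave_rate(w)
#' wave_duration(w)
#' @export
waveform <- function(samples, rate, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    rlang::abort("`samples` must have length >= 1.")
  }
  if (!all(is.finite(samples))) {
    rlang::abort("`samples` must be finite.")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    rlang::abort("`rate` must be a single positive number (Hz).")
  }
  new_waveform(samples, rate, label)
}

new_waveform <- function(samples, rate, label = "") {
  out <- tibble::tibble(
    time = (seq_along(samples) - 1) / rate,
    value = samples
  )
  attr(out, "rate") <- rate
  attr(out, "label") <- label
  class(out) <- c("waveform", class(out))
  out
}

#' @rdname waveform
#' @param w a `waveform`.
#' @export
wave_rate <- function(w) attr(w, "rate")

#' @rdname waveform
#' @export
wave_label <- function(w) attr(w, "label")

#' @rdname waveform
#' @export
wave_values <- function(w) w[["value"]]

#' @rdname waveform
#' @export
wave_duration <- function(w) nrow(w) / wave_rate(w)

#' Root-mean-square amplitude of a waveform
#'
#' RMS over all samples, or over the "active" samples only (those with a
#' non-zero value), which for the synthesized calling song corresponds to the
#' pulse extent because inter-pulse pauses are exact zeros. No detrending is
#' applied; all synthesized signals are zero-mean by construction.
#'
#' @param w a `waveform`.
#' @param active_only if `TRUE`, restrict to samples with `value != 0`.
#' @return RMS amplitude (same units as the samples).
#' @export
wave_rms <- function(w, active_only = FALSE) {
  x <- wave_values(w)
  if (active_only) {
    x <- x[x != 0]
    if (length(x) == 0L) return(0)
  }
  sqrt(mean(x^2))
}

#' Two-channel (ipsi/contralateral petiole) waveform pair
#'
#' Holds the simultaneously "recorded" waveforms at the two petioles, as a
#' tibble with columns `time`, `ipsi`, `contra`, plus the ground-truth
#' signal-path arrival offset (contra minus ipsi, ms) for later delay-recovery
#' checks.
#'
#' @param ipsi,contra `waveform`s of equal rate and length.
#' @param true_delay_ms signal-path arrival offset, contra minus ipsi (ms).
#' @return A `two_channel_waveform` tibble.
#' @export
two_channel_waveform <- function(ipsi, contra, true_delay_ms = NA_real_) {
  if (!isTRUE(all.equal(wave_rate(ipsi), wave_rate(contra))) ||
      nrow(ipsi) != nrow(contra)) {
    rlang::abort("`ipsi` and `contra` must share rate and length.")
  }
  out <- tibble::tibble(
    time = ipsi[["time"]],
    ipsi = wave_values(ipsi),
    contra = wave_values(contra)
  )
  attr(out, "rate") <- wave_rate(ipsi)
  attr(out, "true_delay_ms") <- true_delay_ms
  class(out) <- c("two_channel_waveform", class(out))
  out
}

#' Extract one channel of a two-channel waveform
#'
#' @param tc a `two_channel_waveform`.
#' @param channel `"ipsi"` or `"contra"`.
#' @return A `waveform` labelled with the channel name.
#' @export
channel_waveform <- function(tc, channel = c("ipsi", "contra")) {
  channel <- match.arg(channel)
  new_waveform(tc[[channel]], attr(tc, "rate"), channel)
}

#' @rdname two_channel_waveform
#' @param tc a `two_channel_waveform`.
#' @export
true_delay_ms <- function(tc) attr(tc, "true_delay_ms")
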
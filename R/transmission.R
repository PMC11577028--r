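#' Transmission-channel specification
#'
#' One petiole channel of the plant surrogate. The channel applies, in order:
#' a broadband gain, an optional second-order Butterworth low-pass (plants act
#' as low-pass media), an optional explicit linear filter, a pure propagation
#' delay (implemented as a frequency-domain phase shift, so sub-sample delays
#' are exact), and an optional static quadratic nonlinearity emulating
#' harmonic generation by resonating plant tissue. The signal and noise paths
#' share the filter and gain but have independent delays, reflecting the
#' playback geometry in which the song is driven into the ipsilateral leaf
#' while the noise enters at the stem (roughly equidistant from both
#' petioles, hence `noise_delay_ms = 0` by default).
#'
#' @param delay_ms signal-path propagation delay (ms, >= 0).
#' @param gain_db broadband gain (dB; negative = attenuation).
#' @param lp_corner_hz corner frequency of the low-pass (Hz), or `NULL` for
#'   none.
#' @param filt optional explicit filter as `list(b = , a = )` transfer-function
#'   coefficients (set `a = 1` for FIR taps); must be stable.
#' @param nl_coeff quadratic nonlinearity coefficient; the channel output `y`
#'   becomes `y + nl_coeff * y^2`. 0 disables it.
#' @param noise_delay_ms noise-path propagation delay (ms, >= 0).
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(delay_ms = 0, gain_db = 0, lp_corner_hz = NULL,
                         filt = NULL, nl_coeff = 0, noise_delay_ms = 0) {
  if (delay_ms < 0 || noise_delay_ms < 0) {
    rlang::abort("Delays must be >= 0.")
  }
  if (!is.null(filt)) {
    if (!is.list(filt) || is.null(filt$b) || is.null(filt$a)) {
      rlang::abort("`filt` must be a list with elements `b` and `a`.")
    }
    a <- as.numeric(filt$a)
    if (length(a) > 1L) {
      poles <- polyroot(rev(a))
      if (any(Mod(poles) >= 1)) {
        rlang::abort("`filt` is unstable: poles must lie inside the unit circle.")
      }
    }
  }
  if (!is.null(lp_corner_hz)) check_positive_scalar(lp_corner_hz, "lp_corner_hz")
  structure(
    list(delay_ms = delay_ms, gain_db = gain_db, lp_corner_hz = lp_corner_hz,
         filt = filt, nl_coeff = nl_coeff, noise_delay_ms = noise_delay_ms),
    class = "channel_spec"
  )
}

#' Built-in plant transmission presets
#'
#' Two parameter sets standing in for two physical plants with different
#' transmission properties (substrate heterogeneity): `plantA` is a brighter,
#' faster path (low-pass corner 1200 Hz, ipsi/contra signal delays 0.5/1.5 ms,
#' contralateral side 3 dB down), `plantB` a duller, slower one (corner
#' 700 Hz, delays 0.5/2.5 ms, contralateral side 6 dB down). In both, the two
#' channels share the same filter so the inter-petiole delay difference (1 ms
#' for `plantA`, 2 ms for `plantB`) is preserved exactly, and the noise path
#' has no delay difference.
#'
#' @param name `"plantA"` or `"plantB"`.
#' @return A list with elements `ipsi` and `contra` ([channel_spec()]s) and
#'   `name`.
#' @export
transmission_preset <- function(name = c("plantA", "plantB")) {
  name <- match.arg(name)
  switch(name,
    plantA = list(
      name = "plantA",
      ipsi = channel_spec(delay_ms = 0.5, gain_db = 0, lp_corner_hz = 1200),
      contra = channel_spec(delay_ms = 1.5, gain_db = -3, lp_corner_hz = 1200)
    ),
    plantB = list(
      name = "plantB",
      ipsi = channel_spec(delay_ms = 0.5, gain_db = 0, lp_corner_hz = 700),
      contra = channel_spec(delay_ms = 2.5, gain_db = -6, lp_corner_hz = 700)
    )
  )
}

# circular frequency-domain delay; exact for sub-sample shifts
delay_samples <- function(x, delay_s, rate) {
  if (delay_s == 0) return(x)
  n <- length(x)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) * rate / n
  h <- exp(-2i * pi * f * delay_s)
  if (n %% 2 == 0) h[n / 2 + 1] <- cos(2 * pi * f[n / 2 + 1] * delay_s)
  Re(stats::fft(stats::fft(as.complex(x)) * h, inverse = TRUE)) / n
}

apply_channel <- function(x, spec, rate, path = c("signal", "noise")) {
  path <- match.arg(path)
  y <- x * 10^(spec$gain_db / 20)
  if (!is.null(spec$lp_corner_hz)) {
    w <- min(spec$lp_corner_hz / (rate / 2), 0.99)
    bf <- signal::butter(2, w, type = "low")
    y <- as.numeric(signal::filter(bf, y))
  }
  if (!is.null(spec$filt)) {
    y <- as.numeric(signal::filter(spec$filt$b, spec$filt$a, y))
  }
  delay <- if (path == "signal") spec$delay_ms else spec$noise_delay_ms
  delay_samples(y, delay / 1000, rate)
}

#' Propagate stimuli through the two-channel plant surrogate
#'
#' Produces the ipsi- and contralateral petiole waveforms: each channel is the
#' gain-scaled, filtered, delayed signal plus the independently delayed,
#' filtered noise, with the optional per-channel quadratic nonlinearity
#' applied to the sum. The ground-truth signal-path delay difference
#' (`contra$delay_ms - ipsi$delay_ms`) is recorded on the output for delay-
#' recovery checks. Delays are circular (frequency-domain); with stimuli that
#' end in a silent pause only zeros wrap around.
#'
#' @param signal_src source signal `waveform` (e.g. the calling song).
#' @param noise_src source noise `waveform`, already SNR-calibrated (see
#'   [calibrate_noise()]), or `NULL` for a noise-free run. Truncated or
#'   zero-padded to the signal length.
#' @param ipsi,contra [channel_spec()]s for the two petioles. A preset from
#'   [transmission_preset()] supplies both via its `$ipsi`/`$contra`.
#' @return A [two_channel_waveform()].
#' @examples
#' fcs <- synthesize_fcs(n_pulses = 1)
#' p <- transmission_preset("plantA")
#' tc <- transmit(fcs, NULL, p$ipsi, p$contra)
#' true_delay_ms(tc)
#' @export
transmit <- function(signal_src, noise_src = NULL,
                     ipsi = channel_spec(), contra = channel_spec()) {
  stopifnot(inherits(signal_src, "waveform"))
  rate <- wave_rate(signal_src)
  s <- wave_values(signal_src)
  n <- NULL
  if (!is.null(noise_src)) {
    stopifnot(inherits(noise_src, "waveform"))
    if (!isTRUE(all.equal(rate, wave_rate(noise_src)))) {
      rlang::abort("`signal_src` and `noise_src` must share a sampling rate.")
    }
    n <- wave_values(noise_src)
    if (length(n) >= length(s)) {
      n <- n[seq_along(s)]
    } else {
      n <- c(n, numeric(length(s) - length(n)))
    }
  }
  one_channel <- function(spec, label) {
    y <- apply_channel(s, spec, rate, "signal")
    if (!is.null(n)) y <- y + apply_channel(n, spec, rate, "noise")
    if (spec$nl_coeff != 0) y <- y + spec$nl_coeff * y^2
    new_waveform(y, rate, label)
  }
  two_channel_waveform(
    one_channel(ipsi, "ipsi"),
    one_channel(contra, "contra"),
    true_delay_ms = contra$delay_ms - ipsi$delay_ms
  )
}

#' Estimate the inter-channel delay by cross-correlation
#'
#' Circular cross-correlation of the two channels; the lag (restricted to
#' `|lag| <= max_lag_ms`) at which the contralateral channel best matches the
#' ipsilateral one is returned in ms, positive when the contralateral channel
#' lags (arrives later).
#'
#' @param tc a `two_channel_waveform`.
#' @param max_lag_ms search range (ms).
#' @return Estimated delay (ms), at sample resolution.
#' @export
estimate_delay <- function(tc, max_lag_ms = 10) {
  stopifnot(inherits(tc, "two_channel_waveform"))
  rate <- attr(tc, "rate")
  x <- tc[["ipsi"]]
  y <- tc[["contra"]]
  n <- length(x)
  cc <- Re(stats::fft(stats::fft(as.complex(y)) * Conj(stats::fft(as.complex(x))),
                      inverse = TRUE)) / n
  max_lag <- min(floor(max_lag_ms / 1000 * rate), floor(n / 2) - 1)
  lags <- c(0:max_lag, -(max_lag:1))
  idx <- c(1:(max_lag + 1), (n - max_lag + 1):n)
  lags[which.max(cc[idx])] / rate * 1000
}
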
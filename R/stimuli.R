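#' Female calling song specification
#'
#' Parameters of the synthetic female calling song (FCS) of *Nezara viridula*:
#' a train of sinusoidal pulses at the song's fundamental frequency, with
#' linear rise/fall amplitude ramps and silent inter-pulse pauses. Defaults
#' reproduce the playback stimulus used throughout: 1.1 s pulses of an 89 Hz
#' sine with 0.1 s ramps and a 2.8 s pause, at 1 mm/s RMS.
#'
#' @param f0 fundamental frequency (Hz).
#' @param pulse_dur pulse duration (s), ramps included.
#' @param ramp rise and fall time (s); `2 * ramp` must not exceed `pulse_dur`.
#' @param pause silent gap between pulses (s).
#' @param rms_amp target RMS amplitude of the steady-state (unramped) pulse
#'   segment (mm/s). May be 0, giving a silent waveform of the right length.
#' @return An `fcs_spec` list.
#' @export
fcs_spec <- function(f0 = 89, pulse_dur = 1.1, ramp = 0.1, pause = 2.8,
                     rms_amp = 1) {
  check_positive_scalar(f0, "f0")
  check_positive_scalar(pulse_dur, "pulse_dur")
  check_positive_scalar(ramp, "ramp")
  check_positive_scalar(pause, "pause")
  if (!is.numeric(rms_amp) || length(rms_amp) != 1L || !is.finite(rms_amp) ||
      rms_amp < 0) {
    rlang::abort("`rms_amp` must be a single finite number >= 0.")
  }
  if (2 * ramp > pulse_dur) {
    rlang::abort("`ramp` invalid: 2 * ramp must not exceed `pulse_dur`.")
  }
  structure(
    list(f0 = f0, pulse_dur = pulse_dur, ramp = ramp, pause = pause,
         rms_amp = rms_amp),
    class = "fcs_spec"
  )
}

#' Synthesize the female calling song
#'
#' Builds a pulse train: each pulse is a sinusoid at `spec$f0` whose amplitude
#' rises linearly over `spec$ramp`, holds so that the steady-state segment has
#' RMS `spec$rms_amp`, and falls linearly over `spec$ramp`; pulses are
#' separated by `spec$pause` seconds of exact zeros (one pause also follows
#' the final pulse, so pulse onsets are spaced `pulse_dur + pause` apart).
#'
#' @param spec an [fcs_spec()].
#' @param n_pulses number of pulses (>= 1).
#' @param rate sampling rate (Hz); the default 10 kHz is at least 10x the
#'   highest masker band edge used in the experiments.
#' @return A `waveform` labelled `"fcs"`.
#' @examples
#' fcs <- synthesize_fcs(fcs_spec(), n_pulses = 1, rate = 1e4)
#' wave_rms(fcs, active_only = TRUE)
#' @export
synthesize_fcs <- function(spec = fcs_spec(), n_pulses = 1, rate = 10000) {
  if (!inherits(spec, "fcs_spec")) spec <- do.call(fcs_spec, spec)
  if (!is.numeric(n_pulses) || length(n_pulses) != 1L || n_pulses < 1) {
    rlang::abort("`n_pulses` must be >= 1.")
  }
  check_positive_scalar(rate, "rate")
  n_pulse <- round(spec$pulse_dur * rate)
  n_pause <- round(spec$pause * rate)
  t <- (seq_len(n_pulse) - 1) / rate
  env <- pmin(1, t / spec$ramp, (spec$pulse_dur - t) / spec$ramp)
  env <- pmax(env, 0)
  # steady-state RMS of A*sin is A/sqrt(2), so peak amplitude is rms*sqrt(2)
  pulse <- sqrt(2) * spec$rms_amp * env * sin(2 * pi * spec$f0 * t)
  new_waveform(rep(c(pulse, numeric(n_pause)), n_pulses), rate, "fcs")
}

#' Band-limited noise specification
#'
#' Describes one of the masker bands: fundamental-overlapping (FON,
#' 50--150 Hz), fundamental-and-harmonics-overlapping (FHON, 50--500 Hz) or
#' non-overlapping (NON, 500--1000 Hz), together with the target
#' signal-to-noise ratio and a random seed for reproducible synthesis.
#'
#' @param f_lo,f_hi band edges (Hz), `0 < f_lo < f_hi`.
#' @param snr_db target signal-to-noise ratio (dB, RMS-based with the signal
#'   held fixed); carried as metadata, applied by [calibrate_noise()].
#' @param seed integer random seed; `NULL` uses the current RNG state.
#' @return A `noise_band_spec` list.
#' @export
noise_band_spec <- function(f_lo, f_hi, snr_db = NA_real_, seed = NULL) {
  check_positive_scalar(f_lo, "f_lo")
  check_positive_scalar(f_hi, "f_hi")
  if (f_lo >= f_hi) {
    rlang::abort("`f_lo` must be strictly below `f_hi`.")
  }
  structure(
    list(f_lo = f_lo, f_hi = f_hi, snr_db = snr_db, seed = seed),
    class = "noise_band_spec"
  )
}

#' The three canonical masker bands
#'
#' @return Named list of band-edge pairs (Hz): FON 50--150, FHON 50--500,
#'   NON 500--1000.
#' @export
masker_bands <- function() {
  list(FON = c(50, 150), FHON = c(50, 500), NON = c(500, 1000))
}

#' Synthesize band-limited white noise by inverse FFT
#'
#' Builds noise with a flat magnitude spectrum inside `[f_lo, f_hi]` and zero
#' outside: every FFT bin in the band gets unit magnitude and an independent
#' uniform random phase, Hermitian symmetry is enforced so the inverse
#' transform is real, and the result is RMS-normalized to 1 (calibration to a
#' target SNR is a separate step, [calibrate_noise()]).
#'
#' @param spec a [noise_band_spec()]; the band must lie below the Nyquist
#'   frequency `rate / 2`.
#' @param duration length of the noise (s).
#' @param rate sampling rate (Hz).
#' @return A `waveform` with RMS 1, labelled `"noise"`.
#' @examples
#' n <- synthesize_band_noise(noise_band_spec(50, 150, seed = 1), 1, 1e4)
#' wave_rms(n)
#' @export
synthesize_band_noise <- function(spec, duration, rate = 10000) {
  if (!inherits(spec, "noise_band_spec")) spec <- do.call(noise_band_spec, spec)
  check_positive_scalar(duration, "duration")
  check_positive_scalar(rate, "rate")
  if (spec$f_hi >= rate / 2) {
    rlang::abort("`f_hi` must be below the Nyquist frequency rate/2.")
  }
  n <- round(duration * rate)
  if (n < 2L) rlang::abort("`duration` too short for this rate.")
  freqs <- (seq_len(n) - 1) * rate / n
  half <- floor(n / 2)
  pos <- 2:(half + 1) # positive-frequency bins (includes Nyquist when n even)
  in_band <- pos[freqs[pos] >= spec$f_lo & freqs[pos] <= spec$f_hi]
  if (length(in_band) == 0L) {
    rlang::abort("No FFT bin falls inside the band; increase `duration`.")
  }
  spect <- complex(n)
  phases <- with_seed_if(spec$seed, stats::runif(length(in_band), 0, 2 * pi))
  spect[in_band] <- exp(1i * phases)
  if (n %% 2 == 0 && (half + 1) %in% in_band) {
    # Nyquist bin must be real for a real-valued inverse transform
    spect[half + 1] <- if (cos(phases[match(half + 1, in_band)]) >= 0) 1 else -1
  }
  mirror <- in_band[in_band <= half] # exclude Nyquist from mirroring
  spect[n + 2 - mirror] <- Conj(spect[mirror])
  x <- Re(stats::fft(spect, inverse = TRUE)) / n
  x <- x / rms_of(x)
  new_waveform(x, rate, "noise")
}

#' Measure the signal-to-noise ratio of a signal/noise pair
#'
#' SNR in dB as `20 * log10(RMS_signal / RMS_noise)`, both RMS values taken
#' over the signal's active (pulse) extent — the samples where the signal is
#' non-zero — because the calling-song amplitude is held fixed while only the
#' noise amplitude varies.
#'
#' @param signal,noise `waveform`s at the same rate; the noise must be at
#'   least as long as the signal.
#' @return SNR in dB.
#' @export
measure_snr <- function(signal, noise) {
  stopifnot(inherits(signal, "waveform"), inherits(noise, "waveform"))
  if (!isTRUE(all.equal(wave_rate(signal), wave_rate(noise)))) {
    rlang::abort("`signal` and `noise` must share a sampling rate.")
  }
  if (nrow(noise) < nrow(signal)) {
    rlang::abort("`noise` must be at least as long as `signal`.")
  }
  s <- wave_values(signal)
  active <- s != 0
  if (!any(active)) rlang::abort("`signal` has zero RMS.")
  n <- wave_values(noise)[seq_len(nrow(signal))][active]
  rn <- rms_of(n)
  if (rn == 0) rlang::abort("`noise` has zero RMS over the signal extent.")
  20 * log10(rms_of(s[active]) / rn)
}

#' Scale noise to a target signal-to-noise ratio
#'
#' Rescales the noise so that `20 * log10(RMS_signal / RMS_noise)` equals
#' `snr_db`, with both RMS values measured over the signal's active (pulse)
#' extent. The noise is truncated to the signal length. The applied scale
#' factor is stored in the `"scale"` attribute of the result.
#'
#' @inheritParams measure_snr
#' @param snr_db target SNR (dB); lower values mean louder noise.
#' @return The scaled noise `waveform` (attribute `"scale"` holds the factor).
#' @export
calibrate_noise <- function(signal, noise, snr_db) {
  if (!is.numeric(snr_db) || length(snr_db) != 1L || !is.finite(snr_db)) {
    rlang::abort("`snr_db` must be a single finite number.")
  }
  snr_now <- measure_snr(signal, noise) # validates inputs
  scale <- 10^((snr_now - snr_db) / 20)
  out <- new_waveform(wave_values(noise)[seq_len(nrow(signal))] * scale,
                      wave_rate(noise), wave_label(noise))
  attr(out, "scale") <- scale
  out
}

#' Mix a signal with SNR-calibrated noise
#'
#' Convenience wrapper: calibrates the noise to `snr_db` with
#' [calibrate_noise()] and returns `signal + scaled noise`. The noise scale
#' factor is reported in the `"scale"` attribute of the mixture.
#'
#' @inheritParams calibrate_noise
#' @return A `waveform` mixture (attribute `"scale"` holds the noise scale).
#' @export
calibrate_and_mix <- function(signal, noise, snr_db) {
  scaled <- calibrate_noise(signal, noise, snr_db)
  out <- new_waveform(wave_values(signal) + wave_values(scaled),
                      wave_rate(signal), "mixture")
  attr(out, "scale") <- attr(scaled, "scale")
  out
}
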
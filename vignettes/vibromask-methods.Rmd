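---
title: "Modelling noise masking of substrate-borne vibrational signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling noise masking of substrate-borne vibrational signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Female southern green stink bugs (*Nezara viridula*) advertise with a pulsed
vibrational calling song transmitted through the host plant: trains of 1.1 s
sinusoidal pulses at an 89 Hz fundamental, separated by 2.8 s pauses. Males
read two things from this signal: its *identity*, carried by the
spectro-temporal pulse structure, and the female's *direction*, carried by
the sub-millisecond difference in arrival time of the vibration at receptors
in different legs. Broadband substrate noise — wind, rain, machinery —
can mask both. This package implements a desk-scale model of that masking
chain: stimulus synthesis, a parametric plant surrogate, a threshold-crossing
receptor-neuron model, and the spike-train statistics used to quantify how
much of the signal survives.

```{r, eval = FALSE}
library(vibromask)
fcs <- synthesize_fcs(fcs_spec(), n_pulses = 2)
autoplot(fcs)
```

## Stimuli

`synthesize_fcs()` builds the song from an `fcs_spec()`: a sinusoid at `f0`
(default 89 Hz) with linear amplitude ramps of `ramp` (0.1 s) at pulse onset
and offset, a pulse length of `pulse_dur` (1.1 s), and `pause` (2.8 s) of
exact zeros after each pulse. The steady-state segment is scaled to RMS
`rms_amp` (default 1 mm/s, the playback level used at the reference point).
Linear ramps are the simplest defensible envelope; nothing downstream depends
on the exact ramp shape because detection thresholds sit well inside the
steady segment's amplitude.

`synthesize_band_noise()` makes the maskers by inverse FFT: unit magnitude
and independent uniform random phases in every frequency bin inside the band,
zero outside, Hermitian symmetry, inverse transform, RMS normalized to 1.
Spectral flatness inside the band therefore holds *by construction* — the
surrogate has no physical plant whose response would need manual flattening.
The three canonical bands (`masker_bands()`) are FON (50–150 Hz, overlapping
the song fundamental), FHON (50–500 Hz, covering fundamental and harmonics)
and NON (500–1000 Hz, spectrally disjoint from the song).

`calibrate_noise()` scales a masker to a target SNR, defined as
$\mathrm{SNR} = 20\log_{10}(\mathrm{RMS}_{sig}/\mathrm{RMS}_{noise})$ with
both RMS values measured over the signal's *pulse-active* extent (samples
where the song is non-zero). The experimental convention holds the song
amplitude fixed and varies only the noise, so decreasing SNR always means
louder noise; whether the original calibration window covered whole trials
or pulses only is not documented, and the pulse-active choice is fixed here
because the song's own level is defined over its pulses.

## The plant surrogate

Real plants impose unknown, individual transfer functions, and transmission
measurably differs between plants. Rather than fitting any particular plant,
`transmit()` parameterizes the path to each petiole (`channel_spec()`): a
broadband gain, a second-order Butterworth low-pass, an optional explicit
filter, a pure delay, and an optional quadratic nonlinearity
($y \mapsto y + c\,y^2$) standing in for the harmonic generation observed in
resonating plant tissue. Delays are applied as frequency-domain phase
shifts, so sub-sample values are exact; the shift is circular, which is
harmless because synthesized stimuli end in a silent pause.

Two presets emulate a two-plant design. `plantA`: corner 1200 Hz, ipsi/contra
signal delays 0.5/1.5 ms, contralateral gain −3 dB. `plantB`: corner 700 Hz,
delays 0.5/2.5 ms, −6 dB. The delay differences (1 and 2 ms) sit in the range
that the animals' interneurons are known to resolve (0.5 ms and up); the
corner frequencies are high enough that the 500–1000 Hz masker still reaches
the petioles attenuated but present, as it does on real plants. Both channels
of a preset share one filter, so the inter-petiole delay difference — the
directional cue — is preserved exactly and is recorded on the output as
`true_delay_ms` for ground-truthing. The noise path (driven into the stem,
roughly equidistant from both petioles) has zero delay difference by default.
These presets are free parameters of the surrogate, not measurements.

## The threshold-crossing neuron

The receptor model works on RMS-normalized waveforms (`normalize_rms()`,
whole-trace RMS set to 1) so a threshold reads as a multiple of RMS; 0.0,
0.5 and 1.0 × RMS are the standard settings. `detect_events()` defines an
event as a maximal run of samples strictly above threshold — positive-going
only by default, since a spiking afferent rectifies; a `polarity = "both"`
flag rectifies the waveform first. The event timestamp is the run's
*midpoint*, which for a sinusoid is the waveform peak.

A 5 ms refractory period then thins the events, scanning left to right: a
candidate is discarded if its midpoint lies within the dead time of the
previous *accepted* event's midpoint. Measuring the dead time
midpoint-to-midpoint is a deliberate convention: it makes the guarantee
"accepted events are never closer than the refractory period" literally true,
and it reproduces the physiological anchor exactly — a 5 ms dead time caps
one-event-per-cycle following at 200 Hz, the phase-locking limit of these
receptor neurons. The comparison carries a 1 ns guard absorbing
floating-point representation error of midpoint times (midpoints lie on a
half-sample grid, so nothing genuinely sub-refractory can pass).

`interval_distribution()` histograms consecutive midpoint intervals, pooled
across the two petiole trains of a condition, on [refractory, 50 ms] in
0.5 ms bins — the bin width matching the behavioural delay-resolution
context, the 50 ms ceiling excluding the inter-pulse pauses from summaries
of within-pulse structure. For the clean song the distribution collapses
onto 1/f0 ≈ 11.24 ms; masking noise widens it, shifts the mode and raises
secondary peaks.

`pair_delays()` extracts the directional cue. For each ipsilateral event, a
search window runs from the midpoint between it and its predecessor to the
midpoint between it and its successor (recording edges bound the first and
last windows); the closest unpaired contralateral event in the window becomes
its partner and the delay is $t_{contra} - t_{ipsi}$, positive when the
ipsilateral side leads. The procedure then repeats from the still-unpaired
contralateral events, and each event pairs at most once. Two conventions are
fixed where the procedure is underdetermined: equidistant candidates resolve
to the *earlier* event (deterministic), and the second pass builds its
windows from the unpaired contralateral events themselves. Tests verify that
on constructed shifts the algorithm coincides with an independent
globally-closest matcher.

## Spike-train operators

The electrophysiology layer works on `spike_train` objects and mirrors the
analysis applied to recorded leg-nerve activity:

* `kernel_rate()` — the PSTH: every spike becomes a unit-area Gaussian of SD
  `sigma` on a `dt` grid; trials are averaged and the across-trial SD kept.
  Kernels are truncated at the recording edges without renormalization, so
  the estimate is biased low within ~3σ of the edges; everywhere else the
  integral of one trial's curve recovers its spike count (tested to 1%).
  The kernel SD is not documented for the original analysis; the defaults —
  σ = 5 ms for rate curves, σ = 1 ms for spectral pre-smoothing — are chosen
  to resolve the 89 Hz period while suppressing bin noise, and are
  configurable.
* `spike_psd()` — periodogram of the kernel-convolved, mean-subtracted rate
  of a single train; frequency resolution 1/duration. The 1 ms pre-smoothing
  also attenuates harmonics of a periodic train (a delta comb has equal power
  at all harmonics; the Gaussian factor $e^{-(2\pi f\sigma)^2}$ makes the
  fundamental dominate), so the spectrum of a phase-locked response peaks at
  89 Hz.
* `normalized_f0_power()` — power in the bin containing f0, normalized to
  the same bin of a control spectrum. The original normalization convention
  is stated only as "normalised"; normalizing to the no-noise control per
  preparation is this package's interpretation, and identity inputs give
  exactly 1.
* `relative_response()` — mean over a window of (rate with signal+noise −
  rate with noise alone), the signal-attributable response; it may be
  negative.
* `simulate_phase_locked_train()` — the generator that makes all of the
  above testable without recordings: one spike per stimulus cycle at a fixed
  phase plus Gaussian jitter, optional thinning to a target mean rate,
  optional Poisson background. At zero jitter it is exactly periodic (vector
  strength 1); at large jitter it converges to Poisson-like statistics.

## The experiment grid

`experiment_grid()` crosses noise band × SNR × threshold × plant preset.
Defaults span the full study design: three bands, SNR ∈ {24, 18, 12, 6, 0,
−6} dB (the physiological 24–0 dB range in 6 dB steps plus the lowest
behavioural level), thresholds {0, 0.5, 1} × RMS, both presets, and
noise-free control cells. `run_grid()` executes each cell — synthesize,
calibrate, transmit, normalize, detect, summarize — and returns a tidy
long-format table plus a seed log. Per-cell seeds are derived by hashing the
cell coordinates with the master seed, so any cell reruns bit-identically in
isolation. Beyond the modal interval and modal delay, the table carries
derived summaries that quantify "the distribution widened": the interval
IQR, the fraction of intervals within one bin of 1/f0, and the fraction of
delays within 0.25 ms of the ground-truth delay. `masking_onset()` condenses
these into the highest SNR at which the interval IQR exceeds twice its
noise-free control — for spectrally overlapping maskers this breakdown sets
in at weaker noise than for the non-overlapping band.

Default grid runs use 3 song pulses per cell at 10 kHz (the replicate
analyses in the test-suite use 2), sizes at which every metric of interest —
interval mode and IQR, delay concentration — is already stable to well
within the bin width: one pulse contributes ~98 song cycles per channel.

One caveat on the control IQR: a noise-free control at threshold 1.0 is so
regular that its interval IQR is quantization-limited (a fraction of one
sample). Doubling a near-zero control is a low bar, so the onset SNR
saturates at the highest tested level for all bands; the ordering property
(overlapping ≥ non-overlapping) is still the meaningful, and tested,
statement.

## What the generators do and do not emulate

The synthetic stimuli reproduce the playback design: exact pulse timing,
in-band-flat maskers, RMS-based SNR calibration. The plant surrogate
reproduces delay, attenuation, low-pass filtering and optional harmonic
generation, but not dispersion, frequency-dependent propagation speed,
standing-wave amplitude patterns along the stem, or plant-to-plant transfer
functions beyond the two presets. The phase-locked spike generator emulates
a single ideally locking unit, whereas recorded leg-nerve activity is a
summed response of multiple receptor types with adaptation. Passing tests
therefore demonstrate that the *operators and the model* behave correctly
and reproduce the study-level orderings under controlled conditions — not
that any particular plant or preparation is quantitatively matched.

## Interfaces

The package's interface is its functions, composed with the pipe; `run_grid()`
writes `results.csv`, `histograms.csv` and `run_log.csv` for downstream use,
and `write_wav()`/`read_wav()` exchange waveforms with external tools as
float PCM WAV with a JSON metadata sidecar. All result types are tibbles
with `autoplot()`, and model objects have `tidy()`/`glance()` methods.
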
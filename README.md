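# vibromask

Noise masking of substrate-borne vibrational communication, modelled at the
desk. Female southern green stink bugs (*Nezara viridula*) call through the
host plant with trains of 1.1 s, 89 Hz sinusoidal pulses; searching males
decode the song's identity from its pulse/interval structure and the
female's direction from sub-millisecond arrival-time differences between
legs on different petioles. `vibromask` is for sensory ecologists and
neuroethologists who want to ask, quantitatively: *how much band-limited
substrate noise does it take to destroy each of those codes?*

The package provides, end to end:

* **Stimuli** — the calling song (`synthesize_fcs()`), band-limited
  white-noise maskers built by inverse FFT with random phases
  (`synthesize_band_noise()`: FON 50–150 Hz, FHON 50–500 Hz, NON
  500–1000 Hz), and RMS-based SNR calibration with the signal held fixed
  (`calibrate_noise()`, `measure_snr()`), where
  SNR = 20·log₁₀(RMS_sig/RMS_noise).
* **A plant surrogate** — `transmit()` maps source stimuli to the two
  petioles through parametric channels (delay, gain, low-pass, optional
  quadratic nonlinearity), with ground-truth delays recorded.
* **A receptor model** — `detect_events()`: threshold crossings of the
  RMS-normalized waveform (thresholds 0, 0.5, 1 × RMS), timestamped at the
  crossing-run midpoint, thinned by a 5 ms refractory period — the dead time
  that caps one-event-per-cycle phase locking at 200 Hz. Interval
  distributions (`interval_distribution()`) and ipsi/contra delay pairing
  (`pair_delays()`) quantify the two codes.
* **Spike-train operators** — Gaussian-kernel PSTH (`kernel_rate()`),
  spike-train power spectra (`spike_psd()`), normalized 89 Hz power
  (`normalized_f0_power()`), relative response (`relative_response()`), and
  a phase-locked train simulator so everything is testable without
  recordings.
* **An experiment runner** — `run_grid()` crosses band × SNR × threshold ×
  plant preset with reproducible per-cell seeds and returns tidy long-format
  tables; `masking_onset()` finds the SNR at which interval structure first
  breaks down.

Everything is tibble-in/tibble-out with `autoplot()`, `tidy()` and
`glance()` methods.

## Worked example

Mask the song with fundamental-overlapping noise at 0 dB SNR on the
`plantA` preset and inspect both codes:

```r
library(vibromask)

fcs   <- synthesize_fcs(fcs_spec(), n_pulses = 2)          # 89 Hz song
plant <- transmission_preset("plantA")
noise <- synthesize_band_noise(noise_band_spec(50, 150, seed = 42),
                               wave_duration(fcs))
petioles <- transmit(fcs, calibrate_noise(fcs, noise, snr_db = 0),
                     plant$ipsi, plant$contra)

ev <- lapply(c("ipsi", "contra"), function(ch)
  detect_events(normalize_rms(channel_waveform(petioles, ch)), threshold = 1))
glance(ev[[1]])
#> # A tibble: 1 × 6
#>   n_events min_interval_ms median_interval_ms threshold refractory duration
#>      <int>           <dbl>              <dbl>     <dbl>      <dbl>    <dbl>
#> 1      458            5.55               13.2         1      0.005      7.8

glance(pair_delays(ev[[1]], ev[[2]]))
#> # A tibble: 1 × 4
#>   n_pairs n_unpaired median_delay_ms frac_positive
#>     <int>      <int>           <dbl>         <dbl>
#> 1     451          9               0         0.344
```

Without noise the interval distribution sits on the song period
(modal interval 11.25 ms ≈ 1/89 Hz, IQR 0.05 ms) and every paired delay
equals the 1 ms ground-truth petiole delay. At 0 dB the interval IQR has
exploded to 9.55 ms and the delay code has collapsed to chance
(`median_delay_ms` 0, only 34% of delays still positive): the noise has
masked both the song's period and its direction. The spectral side behaves
the same way —

```r
train <- simulate_phase_locked_train(89, duration = 10, lock_jitter = 0.001,
                                     seed = 1)
glance(spike_psd(train))
#> # A tibble: 1 × 3
#>   peak_f peak_power resolution_hz
#>    <dbl>      <dbl>         <dbl>
#> 1     89  82297066.           0.1
```

— a phase-locked train's power spectrum peaks exactly at the 89 Hz song
fundamental, and `normalized_f0_power()` tracks how jitter or masking erodes
that peak. `run_grid(experiment_grid())` runs the full design and
`plot_grid_metric()` summarizes any metric across conditions.

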
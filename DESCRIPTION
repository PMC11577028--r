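Package: vibromask
Title: Vibrational Noise Masking Analysis for Substrate-Borne Insect Communication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how band-limited substrate noise masks the
    pulsed vibrational calling song of the southern green stink bug (Nezara
    viridula). Synthesizes the female calling song (89 Hz ramped sine pulses)
    and band-limited white-noise maskers calibrated to target signal-to-noise
    ratios, propagates them through a parametric two-channel plant-transmission
    surrogate (ipsi- and contralateral petioles), runs a threshold-crossing
    model of a phase-locking vibroreceptor neuron with a refractory period,
    and analyses the resulting event trains: inter-event interval
    distributions, ipsi-contra time-delay pairing, Gaussian-kernel rate
    estimates (PSTH), spike-train power spectra, normalized signal-frequency
    power and relative response. Includes a phase-locked spike-train simulator
    and an experiment-grid runner that emits tidy result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
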
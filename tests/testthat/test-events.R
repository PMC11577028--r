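test_that("RMS normalization is exact, scale-invariant and rejects silence", {
  rate <- 1e4
  t <- seq(0, 1 - 1 / rate, by = 1 / rate)
  # amplitude sqrt(2) sine already has RMS 1: fixed point
  w <- waveform(sqrt(2) * sin(2 * pi * 89 * t), rate)
  expect_equal(wave_values(normalize_rms(w)), wave_values(w), tolerance = 1e-9)
  # scale invariance
  w7 <- waveform(wave_values(w) * 7, rate)
  expect_equal(wave_values(normalize_rms(w7)), wave_values(normalize_rms(w)),
               tolerance = 1e-12)
  # random fixture: output RMS recomputed directly is 1
  set.seed(31)
  g <- normalize_rms(waveform(rnorm(5000), rate))
  expect_equal(sqrt(mean(wave_values(g)^2)), 1, tolerance = 1e-9)
  expect_error(normalize_rms(waveform(numeric(10) + 0, rate)), "all-zero")
})

test_that("a unit-RMS sine at the song fundamental yields one event per cycle", {
  rate <- 1e4
  t <- seq(0, 1 - 1 / rate, by = 1 / rate)
  w <- normalize_rms(waveform(sin(2 * pi * 89 * t), rate))
  ev <- detect_events(w, threshold = 1, refractory = 0.005)
  expect_equal(nrow(ev), 89)
  iv <- diff(ev$midpoint)
  expect_true(all(abs(iv - 1 / 89) <= 1 / rate))
})

test_that("refractory filtering rejects alternate cycles of a 250 Hz sine", {
  rate <- 1e4
  t <- seq(0, 1 - 1 / rate, by = 1 / rate)
  # small phase offset keeps samples off the exact threshold boundary
  w <- normalize_rms(waveform(sin(2 * pi * 250 * t + 0.1), rate))
  ev <- detect_events(w, threshold = 1, refractory = 0.005)
  expect_equal(nrow(ev), 125) # half of the 250 cycles
  expect_true(all(abs(diff(ev$midpoint) - 0.008) <= 1 / rate))
  # brute-force sequential-scan oracle agrees exactly
  oracle <- brute_force_detect(wave_values(w), rate, 1, 0.005)
  expect_equal(ev$midpoint, oracle$midpoint)
  expect_equal(ev$onset, oracle$onset)
})

test_that("detection matches the brute-force oracle on random fixtures", {
  rate <- 2e3
  set.seed(100)
  for (k in 1:25) {
    x <- rnorm(rate) # 1 s fixture
    w <- normalize_rms(waveform(x, rate))
    thr <- sample(c(0, 0.5, 1), 1)
    ev <- detect_events(w, thr, 0.005)
    oracle <- brute_force_detect(wave_values(w), rate, thr, 0.005)
    expect_equal(ev$midpoint, as.numeric(oracle$midpoint))
    expect_equal(ev$onset, as.numeric(oracle$onset))
  }
})

test_that("constant sub-threshold input yields no events, and settings are recorded", {
  w <- waveform(numeric(1000) + 0.1, 1e3)
  ev <- detect_events(w, threshold = 0.5)
  expect_equal(nrow(ev), 0)
  expect_equal(attr(ev, "threshold"), 0.5)
  expect_equal(attr(ev, "refractory"), 0.005)
})

test_that("threshold 0 selects positive half-waves and polarity flag rectifies", {
  rate <- 1e4
  t <- seq(0, 0.5 - 1 / rate, by = 1 / rate)
  w <- normalize_rms(waveform(sin(2 * pi * 50 * t), rate))
  ev0 <- detect_events(w, threshold = 0, refractory = 0.005)
  expect_equal(nrow(ev0), 25) # one positive half-wave per 20 ms cycle
  ev_both <- detect_events(w, threshold = 0.5, refractory = 0.001,
                           polarity = "both")
  ev_pos <- detect_events(w, threshold = 0.5, refractory = 0.001)
  expect_equal(nrow(ev_both), 2 * nrow(ev_pos))
})

test_that("raising the threshold never increases the event count", {
  set.seed(7)
  for (k in 1:10) {
    w <- normalize_rms(waveform(rnorm(4000), 2e3))
    counts <- vapply(c(0, 0.5, 1, 1.5, 2),
                     function(th) nrow(detect_events(w, th, 0.005)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("accepted midpoints are never closer than the refractory period", {
  set.seed(8)
  for (k in 1:10) {
    w <- normalize_rms(waveform(rnorm(5000), 2e3))
    ev <- detect_events(w, 0.5, 0.005)
    if (nrow(ev) > 1) expect_gte(min(diff(ev$midpoint)), 0.005 - 1e-9)
  }
})

test_that("interval histograms pool trains and count hand-checkable cases", {
  # single train with events at 0, 10, 20 ms: two 10 ms intervals in one bin
  tr <- detect_events(normalize_rms(waveform(rep(c(5, rep(0, 9)), 3), 1e3)),
                      threshold = 1, refractory = 0.005)
  expect_equal(tr$midpoint, c(0, 0.01, 0.02))
  h <- interval_distribution(tr, bin_ms = 0.5)
  expect_equal(sum(h$count), 2)
  expect_equal(h$count[h$bin_lo_ms <= 10 & h$bin_hi_ms > 10], 2)

  # pooling two copies doubles every count
  h2 <- interval_distribution(list(tr, tr), bin_ms = 0.5)
  expect_equal(sum(h2$count), 4)

  # fewer than 2 events everywhere: empty histogram with a warning
  empty <- detect_events(waveform(numeric(100), 1e3), 0.5)
  expect_warning(he <- interval_distribution(empty), "empty")
  expect_equal(sum(he$count), 0)
})

test_that("noise-free song pair gives a unimodal interval histogram at 1/f0", {
  fcs <- synthesize_fcs(n_pulses = 2)
  preset <- transmission_preset("plantA")
  tc <- transmit(fcs, NULL, preset$ipsi, preset$contra)
  evs <- lapply(c("ipsi", "contra"), function(ch) {
    detect_events(normalize_rms(channel_waveform(tc, ch)), 1, 0.005)
  })
  h <- interval_distribution(evs, bin_ms = 0.5)
  top <- which.max(h$count)
  expect_true(h$bin_lo_ms[top] <= 1000 / 89 && h$bin_hi_ms[top] > 1000 / 89)
  # near-unimodal: modal bin plus neighbours hold > 90% of intervals
  expect_gt(sum(h$count[pmax(top - 1, 1):pmin(top + 1, nrow(h))]) / sum(h$count),
            0.9)
})

test_that("noise widens the interval distribution relative to the clean song", {
  fcs <- synthesize_fcs(n_pulses = 2)
  preset <- transmission_preset("plantA")
  iqr_of <- function(noise) {
    tc <- transmit(fcs, noise, preset$ipsi, preset$contra)
    iv <- event_intervals(lapply(c("ipsi", "contra"), function(ch) {
      detect_events(normalize_rms(channel_waveform(tc, ch)), 1, 0.005)
    }))$interval_ms
    iv <- iv[iv <= 50]
    unname(diff(quantile(iv, c(0.25, 0.75))))
  }
  clean <- iqr_of(NULL)
  raw <- synthesize_band_noise(noise_band_spec(50, 150, seed = 21),
                               wave_duration(fcs), 1e4)
  loud <- iqr_of(calibrate_noise(fcs, raw, -6))
  expect_gt(loud, clean)
})
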
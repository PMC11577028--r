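test_that("a single spike yields the closed-form Gaussian rate curve", {
  tr <- spike_train(1, duration = 2)
  r <- kernel_rate(tr, sigma = 0.005, dt = 0.001)
  expect_equal(max(r$rate), 1 / (0.005 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(r$t[which.max(r$rate)], 1)
  # unit area
  expect_equal(sum(r$rate) * 0.001, 1, tolerance = 0.01)
})

test_that("the kernel rate recovers a homogeneous Poisson rate and conserves counts", {
  tr <- simulate_poisson_train(100, duration = 20, seed = 5)
  r <- kernel_rate(tr, sigma = 0.005, dt = 0.001)
  expect_equal(mean(r$rate), 100, tolerance = 0.05)
  expect_equal(sum(r$rate) * attr(r, "dt"), nrow(tr), tolerance = 0.01)
})

test_that("trial averaging returns mean and across-trial spread", {
  trains <- lapply(1:5, function(k) {
    simulate_phase_locked_train(89, 1, lock_jitter = 1e-3, seed = 100 + k,
                                trial = paste0("t", k))
  })
  r <- kernel_rate(trains)
  expect_equal(attr(r, "n_trials"), 5)
  expect_true(all(is.finite(r$sd)))
  expect_true(all(r$rate >= 0))
})

test_that("an adapting response shows an onset peak followed by a decline", {
  # step rate 200 -> exponential decay to 60 spikes/s: thinned cycle spikes
  set.seed(42)
  f0 <- 200
  tt <- seq(0.5, 3, by = 1 / f0)
  p <- (60 + 140 * exp(-(tt - 0.5) / 0.3)) / f0
  times <- tt[runif(length(tt)) < p]
  r <- kernel_rate(spike_train(times, 3), sigma = 0.02, dt = 0.001)
  peak_t <- r$t[which.max(r$rate)]
  expect_lt(peak_t, 1) # peak near stimulus onset
  late <- mean(r$rate[r$t > 2 & r$t < 2.8])
  expect_lt(late, 0.6 * max(r$rate)) # clear decline after the peak
  expect_gt(late, 20) # but not silence
})

test_that("the spike-train spectrum peaks at the locking frequency", {
  for (f0 in c(50, 89, 150, 200)) {
    tr <- simulate_phase_locked_train(f0, duration = 10, lock_jitter = 1e-3,
                                      seed = 7)
    expect_lt(abs(peak_frequency(spike_psd(tr)) - f0), 0.2)
  }
})

test_that("timing jitter strictly reduces power at the locking frequency", {
  p_at_f0 <- function(jit) {
    tr <- simulate_phase_locked_train(89, 10, lock_jitter = jit, seed = 11)
    s <- spike_psd(tr)
    s$power[which.min(abs(s$f - 89))]
  }
  expect_gt(p_at_f0(0), p_at_f0(0.002))
})

test_that("a Poisson train has no dominant spectral line", {
  tr <- simulate_poisson_train(89, duration = 10, seed = 3)
  s <- spike_psd(tr)
  p <- s$power[s$f > 0]
  # permutation null: regenerate Poisson trains, collect max/median ratios
  null_ratios <- vapply(1:20, function(k) {
    sk <- spike_psd(simulate_poisson_train(89, 10, seed = 1000 + k))
    pk <- sk$power[sk$f > 0]
    max(pk) / median(pk)
  }, numeric(1))
  expect_lt(max(p) / median(p), 2 * max(null_ratios))
  # while a locked train of the same rate exceeds the null by far
  locked <- spike_psd(simulate_phase_locked_train(89, 10, seed = 4))
  pl <- locked$power[locked$f > 0]
  expect_gt(max(pl) / median(pl), 10 * max(null_ratios))
})

test_that("normalized f0 power is 1 at identity and degrades with jitter", {
  control <- spike_psd(simulate_phase_locked_train(89, 10, seed = 9))
  expect_equal(normalized_f0_power(control, control, 89), 1)
  # averaged over replicates, the ratio is non-increasing in jitter
  jits <- c(0, 5e-4, 1e-3, 2e-3, 4e-3)
  avg <- vapply(jits, function(j) {
    mean(vapply(1:20, function(k) {
      s <- spike_psd(simulate_phase_locked_train(89, 10, lock_jitter = j,
                                                 seed = 200 + k))
      normalized_f0_power(s, control, 89)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(avg) < 0))
  # an unlocked train of equal rate retains almost none of the control power
  pois <- spike_psd(simulate_poisson_train(89, 10, seed = 10))
  expect_lt(normalized_f0_power(pois, control, 89), 0.05)
})

test_that("relative response measures the rate difference over a window", {
  a <- kernel_rate(simulate_poisson_train(150, 20, seed = 21))
  b <- kernel_rate(simulate_poisson_train(50, 20, seed = 22))
  expect_equal(relative_response(a, b, c(1, 19)), 100, tolerance = 0.1)
  expect_equal(relative_response(a, a, c(1, 19)), 0)
})

test_that("a rising noise-driven baseline shrinks the relative response", {
  # saturating receptor: the noise-driven background climbs the rate ceiling,
  # leaving ever less headroom for the signal-driven component
  sat <- function(drive) 140 * drive / (drive + 60)
  rel <- vapply(c(10, 60, 120), function(bg) {
    sig_noise <- kernel_rate(simulate_poisson_train(sat(80 + bg), 20,
                                                    seed = bg))
    noise_alone <- kernel_rate(simulate_poisson_train(sat(bg), 20,
                                                      seed = bg + 1))
    relative_response(sig_noise, noise_alone, c(1, 19))
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
})

test_that("the phase-locked simulator is exact in the deterministic limit", {
  tr <- simulate_phase_locked_train(89, duration = 1)
  expect_equal(nrow(tr), 89)
  expect_equal(tr$time, (0:88) / 89)
  expect_equal(vector_strength(tr$time, 89), 1, tolerance = 1e-12)
  # heavy jitter destroys locking: vector strength near the Poisson level
  noisy <- simulate_phase_locked_train(89, duration = 10, lock_jitter = 0.05,
                                       seed = 2)
  expect_lt(vector_strength(noisy$time, 89), 0.1)
  # thinning reaches the requested mean rate
  thin <- simulate_phase_locked_train(89, duration = 50, base_rate = 30,
                                      seed = 3)
  expect_equal(nrow(thin) / 50, 30, tolerance = 0.15)
})

test_that("spike-train inputs are validated", {
  expect_error(spike_train(c(-0.1, 0.5), 1), "within")
  expect_error(kernel_rate(list()), "at least one")
  expect_error(spike_psd(spike_train(0.5, 1)), "at least 2")
  a <- kernel_rate(simulate_poisson_train(50, 2, seed = 1), dt = 0.001)
  b <- kernel_rate(simulate_poisson_train(50, 2, seed = 1), dt = 0.002)
  expect_error(relative_response(a, b, c(0.5, 1.5)), "time grid")
})
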
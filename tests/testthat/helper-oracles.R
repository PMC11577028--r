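# Independent oracles used across tests. These deliberately avoid the
# package's vectorized implementations.

# brute-force event detection: per-sample scan with sequential refractory
# filtering (midpoint-to-midpoint, matching the documented convention)
brute_force_detect <- function(x, rate, threshold, refractory) {
  mids <- c()
  onsets <- c()
  in_run <- FALSE
  run_start <- NA_integer_
  last_mid <- -Inf
  for (i in seq_along(c(x, -Inf))) {
    v <- if (i <= length(x)) x[i] else -Inf
    if (!in_run && v > threshold) {
      in_run <- TRUE
      run_start <- i
    } else if (in_run && v <= threshold) {
      in_run <- FALSE
      mid <- ((run_start + (i - 1)) / 2 - 1) / rate
      if (mid - last_mid >= refractory - 1e-9) {
        mids <- c(mids, mid)
        onsets <- c(onsets, (run_start - 1) / rate)
        last_mid <- mid
      }
    }
  }
  list(onset = onsets, midpoint = mids)
}

# greedy globally-closest matching: repeatedly pair the unpaired (ipsi,
# contra) event pair with the smallest absolute time difference
global_nearest_match <- function(ti, tc) {
  free_i <- rep(TRUE, length(ti))
  free_c <- rep(TRUE, length(tc))
  out <- NULL
  repeat {
    ii <- which(free_i)
    cc <- which(free_c)
    if (!length(ii) || !length(cc)) break
    d <- abs(outer(ti[ii], tc[cc], "-"))
    k <- arrayInd(which.min(d), dim(d))
    out <- rbind(out, c(t_ipsi = ti[ii[k[1]]], t_contra = tc[cc[k[2]]]))
    free_i[ii[k[1]]] <- FALSE
    free_c[cc[k[2]]] <- FALSE
  }
  out
}

# standard vector strength of spike times against a periodic stimulus
vector_strength <- function(times, f0) {
  ph <- 2 * pi * f0 * times
  sqrt(mean(cos(ph))^2 + mean(sin(ph))^2)
}

# fraction of periodogram power inside [f_lo, f_hi] (one-bin slack at edges)
in_band_power_fraction <- function(x, rate, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (0:(n - 1)) * rate / n
  f <- pmin(f, rate - f) # fold to [0, Nyquist]
  df <- rate / n
  sum(p[f >= f_lo - df & f <= f_hi + df]) / sum(p)
}

# periodogram power at (nearest bin to) a target frequency, as a fraction
power_fraction_at <- function(x, rate, f0) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (0:(n - 1)) * rate / n
  half <- f <= rate / 2
  k <- which.min(abs(f[half] - f0))
  p[half][k] / sum(p[half])
}

# build an event_train directly from midpoint times (s)
make_train <- function(mids, duration, channel = "x", refractory = 0.005) {
  out <- tibble::tibble(onset = mids, midpoint = mids)
  attr(out, "threshold") <- 1
  attr(out, "refractory") <- refractory
  attr(out, "rate") <- 1e4
  attr(out, "duration") <- duration
  attr(out, "channel") <- channel
  class(out) <- c("event_train", class(out))
  out
}
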
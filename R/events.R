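#' Normalize a waveform to unit RMS
#'
#' The model neuron's threshold is expressed as a multiple of the waveform's
#' RMS amplitude; normalizing every recording to RMS 1 makes thresholds
#' comparable across channels and noise conditions. RMS is taken over the
#' whole trace.
#'
#' @param w a `waveform` with non-zero RMS.
#' @return The same waveform scaled to RMS 1 (within 1e-9 relative).
#' @export
normalize_rms <- function(w) {
  stopifnot(inherits(w, "waveform"))
  r <- wave_rms(w)
  if (r == 0) rlang::abort("Cannot normalize an all-zero waveform.")
  out <- new_waveform(wave_values(w) / r, wave_rate(w), wave_label(w))
  attrs <- attributes(w)
  for (nm in setdiff(names(attrs), c("names", "row.names", "class", "rate", "label"))) {
    attr(out, nm) <- attrs[[nm]]
  }
  out
}

#' Detect supra-threshold events with a refractory period
#'
#' The threshold-crossing model of a phase-locking vibroreceptor neuron: an
#' event is a maximal contiguous run of samples exceeding the threshold
#' (positive-going only by default), timestamped at the run's midpoint — akin
#' to spike triggering. Scanning left to right, a candidate event is discarded
#' when its midpoint falls within the refractory dead time of the previous
#' accepted event's midpoint, so accepted midpoints are always at least
#' `refractory` apart; a 5 ms refractory period thus caps one-event-per-cycle
#' following at 200 Hz, the phase-locking limit of *N. viridula* receptor
#' neurons. The refractory comparison carries a one-nanosecond guard so a
#' period exactly equal to the dead time is not rejected by floating-point
#' rounding of midpoint times.
#'
#' @param w a `waveform`, normally RMS-normalized (see [normalize_rms()]) so
#'   that `threshold` reads as a multiple of RMS.
#' @param threshold detection threshold (same units as the samples; a multiple
#'   of RMS for a normalized waveform). Must be >= 0; 0 selects positive
#'   half-waves.
#' @param refractory dead time after an accepted event (s).
#' @param polarity `"positive"` counts only positive-going excursions
#'   (default); `"both"` rectifies the waveform first.
#' @return An `event_train`: tibble with columns `onset` and `midpoint` (s),
#'   attributes `threshold`, `refractory`, `rate`, `duration`, `channel`.
#'   May have zero rows.
#' @examples
#' w <- normalize_rms(waveform(sin(2 * pi * 89 * seq(0, 1, 1e-4)), 1e4))
#' ev <- detect_events(w, threshold = 1, refractory = 0.005)
#' head(diff(ev$midpoint)) # ~ 1/89 s
#' @export
detect_events <- function(w, threshold = 1, refractory = 0.005,
                          polarity = c("positive", "both")) {
  stopifnot(inherits(w, "waveform"))
  polarity <- match.arg(polarity)
  if (threshold < 0) rlang::abort("`threshold` must be >= 0.")
  check_positive_scalar(refractory, "refractory")
  rate <- wave_rate(w)
  x <- wave_values(w)
  if (polarity == "both") x <- abs(x)
  above <- x > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep_run <- runs$values
  starts <- starts[keep_run]
  ends <- ends[keep_run]
  onset <- (starts - 1) / rate
  midpoint <- ((starts + ends) / 2 - 1) / rate
  # refractory filter: midpoint-to-midpoint; 1 ns guard against float
  # rounding of midpoint times (midpoints sit on a half-sample grid, so no
  # genuinely sub-refractory spacing can slip through)
  tol <- 1e-9
  acc <- logical(length(midpoint))
  last <- -Inf
  for (i in seq_along(midpoint)) {
    if (midpoint[i] - last >= refractory - tol) {
      acc[i] <- TRUE
      last <- midpoint[i]
    }
  }
  out <- tibble::tibble(onset = onset[acc], midpoint = midpoint[acc])
  attr(out, "threshold") <- threshold
  attr(out, "refractory") <- refractory
  attr(out, "rate") <- rate
  attr(out, "duration") <- wave_duration(w)
  attr(out, "channel") <- wave_label(w)
  class(out) <- c("event_train", class(out))
  out
}

#' Inter-event intervals of one or more event trains
#'
#' Consecutive-event (midpoint-to-midpoint) intervals, pooled across trains —
#' the pooling mirrors combining the ipsi- and contralateral petiole trains of
#' one stimulus condition.
#'
#' @param trains an `event_train` or a list of them.
#' @return Tibble with columns `channel` and `interval_ms`.
#' @export
event_intervals <- function(trains) {
  if (inherits(trains, "event_train")) trains <- list(trains)
  purrr::map_dfr(trains, function(tr) {
    if (nrow(tr) < 2L) {
      return(tibble::tibble(channel = character(), interval_ms = numeric()))
    }
    tibble::tibble(
      channel = attr(tr, "channel") %||% "",
      interval_ms = diff(tr$midpoint) * 1000
    )
  })
}

#' Histogram of inter-event intervals
#'
#' Pools consecutive-event intervals across the given trains and histograms
#' them on `[refractory, max_ms]` with a fixed bin width. The interval
#' distribution of the noise-free calling song is narrow and centred at the
#' inverse of the song's fundamental frequency; noise widens it, shifts the
#' main peak and raises secondary peaks.
#'
#' @param trains an `event_train` or list of them (shared settings).
#' @param bin_ms bin width (ms); the 0.5 ms default matches the behavioural
#'   delay-resolution context.
#' @param max_ms upper edge of the histogram (ms).
#' @return An `interval_histogram`: tibble with `bin_lo_ms`, `bin_hi_ms`,
#'   `bin_mid_ms`, `count`; attributes `bin_ms`, `pooled_from`, `n_intervals`.
#' @export
interval_distribution <- function(trains, bin_ms = 0.5, max_ms = 50) {
  if (inherits(trains, "event_train")) trains <- list(trains)
  check_positive_scalar(bin_ms, "bin_ms")
  refractory <- attr(trains[[1]], "refractory") %||% 0
  iv <- event_intervals(trains)$interval_ms
  if (length(iv) == 0L) {
    rlang::warn("Fewer than 2 events in every train; empty histogram.")
  }
  lo <- refractory * 1000
  edges <- seq(lo, max_ms + bin_ms, by = bin_ms)
  iv <- iv[iv >= lo & iv < max(edges)]
  counts <- if (length(iv)) {
    tabulate(findInterval(iv, edges), nbins = length(edges) - 1L)
  } else {
    integer(length(edges) - 1L)
  }
  out <- tibble::tibble(
    bin_lo_ms = edges[-length(edges)],
    bin_hi_ms = edges[-1],
    bin_mid_ms = (edges[-1] + edges[-length(edges)]) / 2,
    count = counts
  )
  attr(out, "bin_ms") <- bin_ms
  attr(out, "pooled_from") <- purrr::map_chr(trains, ~ attr(.x, "channel") %||% "")
  attr(out, "n_intervals") <- length(iv)
  class(out) <- c("interval_histogram", class(out))
  out
}

# one pairing pass: for each reference event (in time order), search the
# window spanning from the midpoint between it and its predecessor to the
# midpoint between it and its successor (recording edges for first/last) for
# the closest unpaired partner event; ties go to the earlier partner.
pair_pass <- function(ref, other, other_free, duration) {
  pairs <- list()
  n <- length(ref)
  for (i in seq_len(n)) {
    lo <- if (i == 1L) 0 else (ref[i - 1L] + ref[i]) / 2
    hi <- if (i == n) duration else (ref[i] + ref[i + 1L]) / 2
    cand <- which(other_free & other >= lo & other <= hi)
    if (length(cand) == 0L) next
    d <- abs(other[cand] - ref[i])
    best <- cand[order(d, other[cand])][1L]
    other_free[best] <- FALSE
    pairs[[length(pairs) + 1L]] <- c(ref_t = ref[i], other_t = other[best])
  }
  list(pairs = pairs, other_free = other_free)
}

#' Pair ipsi- and contralateral events into time delays
#'
#' Implements the event-pairing algorithm for the directional cue: around
#' each ipsilateral event, a search window runs from the midpoint between it
#' and its predecessor to the midpoint between it and its successor (the
#' recording edges bound the first and last windows); the closest not-yet-
#' paired contralateral event inside the window becomes its partner, and the
#' delay is `t_contra - t_ipsi` (positive = ipsilateral first). The procedure
#' is then repeated from the remaining unpaired contralateral events
#' symmetrically. Each event pairs at most once; equidistant candidates
#' resolve to the earlier one.
#'
#' @param ipsi,contra `event_train`s from the same recording extent.
#' @return A `delay_set`: tibble with `t_ipsi`, `t_contra` (s) and `delay_ms`,
#'   sorted by ipsilateral time; attribute `n_unpaired` counts events (both
#'   sides) left without a partner.
#' @export
pair_delays <- function(ipsi, contra) {
  stopifnot(inherits(ipsi, "event_train"), inherits(contra, "event_train"))
  duration <- max(attr(ipsi, "duration") %||% Inf,
                  attr(contra, "duration") %||% Inf)
  ti <- ipsi$midpoint
  tc <- contra$midpoint
  empty <- tibble::tibble(t_ipsi = numeric(), t_contra = numeric(),
                          delay_ms = numeric())
  if (length(ti) == 0L || length(tc) == 0L) {
    out <- empty
    attr(out, "n_unpaired") <- length(ti) + length(tc)
    class(out) <- c("delay_set", class(out))
    return(out)
  }
  p1 <- pair_pass(ti, tc, rep(TRUE, length(tc)), duration)
  ipsi_free <- !(ti %in% vapply(p1$pairs, `[[`, numeric(1), "ref_t"))
  p2 <- pair_pass(tc[p1$other_free], ti, ipsi_free, duration)
  rows <- c(
    purrr::map(p1$pairs, ~ tibble::tibble(t_ipsi = .x[["ref_t"]],
                                          t_contra = .x[["other_t"]])),
    purrr::map(p2$pairs, ~ tibble::tibble(t_ipsi = .x[["other_t"]],
                                          t_contra = .x[["ref_t"]]))
  )
  out <- if (length(rows)) dplyr::arrange(dplyr::bind_rows(rows), .data$t_ipsi) else empty
  out$delay_ms <- (out$t_contra - out$t_ipsi) * 1000
  n_paired <- nrow(out)
  attr(out, "n_unpaired") <- (length(ti) - n_paired) + (length(tc) - n_paired)
  class(out) <- c("delay_set", class(out))
  out
}
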
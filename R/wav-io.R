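#' Write a waveform to a WAV file
#'
#' Writes IEEE-float (32-bit) PCM WAV, mono for a `waveform` or stereo for a
#' `two_channel_waveform` (left = ipsi, right = contra). A JSON sidecar
#' (`<path>.json`) records the sampling rate, label or ground-truth delay,
#' and any extra metadata supplied (e.g. a calibration scale factor), since
#' WAV itself carries none of it.
#'
#' @param x a `waveform` or `two_channel_waveform`.
#' @param path output file path.
#' @param meta optional named list of extra metadata for the sidecar.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, meta = list(), sidecar = TRUE) {
  if (inherits(x, "two_channel_waveform")) {
    dat <- rbind(x[["ipsi"]], x[["contra"]]) # interleave L/R
    rate <- attr(x, "rate")
    info <- list(channels = c("ipsi", "contra"),
                 true_delay_ms = true_delay_ms(x))
  } else if (inherits(x, "waveform")) {
    dat <- matrix(wave_values(x), nrow = 1)
    rate <- wave_rate(x)
    info <- list(channels = wave_label(x))
  } else {
    rlang::abort("`x` must be a waveform or two_channel_waveform.")
  }
  n_ch <- nrow(dat)
  n_frames <- ncol(dat)
  data_bytes <- 4L * n_ch * n_frames
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little") # IEEE float
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(round(rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(rate) * 4L * n_ch), con, size = 4, endian = "little")
  writeBin(as.integer(4L * n_ch), con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(as.numeric(dat), con, size = 4, endian = "little")
  if (sidecar) {
    jsonlite::write_json(
      c(list(rate = rate), info, meta),
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read a WAV file as a waveform
#'
#' Reads 32-bit IEEE-float or 16-bit integer PCM WAV (the formats this
#' package writes or users typically supply). Mono files become a `waveform`;
#' stereo files a `two_channel_waveform` (left = ipsi, right = contra). A
#' JSON sidecar written by [write_wav()] is consulted for the label and the
#' ground-truth delay when present.
#'
#' @param path WAV file path.
#' @return A `waveform` or `two_channel_waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") rlang::abort("Not a RIFF/WAVE file.")
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") rlang::abort("Not a RIFF/WAVE file.")
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        format = readBin(con, "integer", size = 2, endian = "little"),
        channels = readBin(con, "integer", size = 2, endian = "little"),
        rate = readBin(con, "integer", size = 4, endian = "little")
      )
      readBin(con, "raw", n = sz - 8L)
    } else if (id == "data") {
      if (is.null(fmt)) rlang::abort("Malformed WAV: data before fmt.")
      if (fmt$format == 3L) {
        samples <- readBin(con, "numeric", n = sz / 4L, size = 4,
                           endian = "little")
      } else if (fmt$format == 1L) {
        samples <- readBin(con, "integer", n = sz / 2L, size = 2,
                           signed = TRUE, endian = "little") / 32768
      } else {
        rlang::abort("Unsupported WAV encoding; use float32 or int16 PCM.")
      }
      break
    } else {
      readBin(con, "raw", n = sz + sz %% 2L)
    }
  }
  if (is.null(samples)) rlang::abort("No data chunk found.")
  side <- paste0(path, ".json")
  info <- if (file.exists(side)) jsonlite::read_json(side) else list()
  if (fmt$channels == 1L) {
    waveform(samples, fmt$rate,
             label = as.character(info$channels %||% ""))
  } else if (fmt$channels == 2L) {
    ip <- samples[seq(1, length(samples), by = 2)]
    co <- samples[seq(2, length(samples), by = 2)]
    two_channel_waveform(
      new_waveform(ip, fmt$rate, "ipsi"),
      new_waveform(co, fmt$rate, "contra"),
      true_delay_ms = as.numeric(info$true_delay_ms %||% NA_real_)
    )
  } else {
    rlang::abort("Only mono or stereo WAV is supported.")
  }
}
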
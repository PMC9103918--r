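#' Read a WAV file
#'
#' Supports RIFF/WAVE with PCM 16/24/32-bit integer or IEEE float 32/64-bit
#' samples (including WAVE_FORMAT_EXTENSIBLE wrappers). Integer samples are
#' scaled by their full-scale value to \[-1, 1\]; multichannel audio is
#' downmixed to mono by averaging channels.
#'
#' @param path Path to the WAV file.
#' @return List with `audio` (numeric vector) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "wdrcnr_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readBin(con, "raw", 4)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size
  wave <- readBin(con, "raw", 4)
  if (!identical(riff, charToRaw("RIFF")) || !identical(wave, charToRaw("WAVE"))) {
    abort(sprintf("Not a RIFF/WAVE file: %s", path), class = "wdrcnr_format_error")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0L || is.na(sz)) break
    if (identical(id, charToRaw("fmt "))) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        code = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
      if (fmt$code == 0xFFFE && sz >= 40) {  # extensible: true format in the GUID
        fmt$code <- readBin(body[25:26], "integer", 1, 2, signed = FALSE,
                            endian = "little")
      }
    } else if (identical(id, charToRaw("data"))) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      seek(con, sz + sz %% 2, origin = "current")
      next
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("Missing fmt/data chunk in %s", path),
          class = "wdrcnr_format_error")
  }
  samples <- decode_wav_samples(data_raw, fmt, path)
  if (fmt$channels > 1L) {
    m <- matrix(samples, nrow = fmt$channels)
    samples <- colMeans(m)
  }
  list(audio = samples, sample_rate = fmt$sample_rate)
}

decode_wav_samples <- function(raw, fmt, path) {
  if (fmt$code == 1L) {
    switch(as.character(fmt$bits),
      "16" = readBin(raw, "integer", length(raw) / 2, 2,
                     signed = TRUE, endian = "little") / 32768,
      "24" = {
        n <- length(raw) / 3
        b <- matrix(as.integer(raw), nrow = 3)
        v <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      },
      "32" = readBin(raw, "integer", length(raw) / 4, 4, endian = "little") / 2147483648,
      abort(sprintf("Unsupported PCM bit depth %d in %s", fmt$bits, path),
            class = "wdrcnr_format_error")
    )
  } else if (fmt$code == 3L) {
    if (fmt$bits == 32L) {
      readBin(raw, "double", length(raw) / 4, 4, endian = "little")
    } else if (fmt$bits == 64L) {
      readBin(raw, "double", length(raw) / 8, 8, endian = "little")
    } else {
      abort(sprintf("Unsupported float bit depth %d in %s", fmt$bits, path),
            class = "wdrcnr_format_error")
    }
  } else {
    abort(sprintf("Unsupported WAV codec (format code %d) in %s", fmt$code, path),
          class = "wdrcnr_format_error")
  }
}

#' Write a mono 32-bit float WAV file
#'
#' @param audio Numeric vector with amplitudes in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, sample_rate, path) {
  if (any(!is.finite(audio)) || any(abs(audio) > 1)) {
    abort("Amplitudes must be finite and within [-1, 1].",
          class = "wdrcnr_invalid_input")
  }
  n <- length(audio)
  data_bytes <- 4L * n
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(3L, con, 2, endian = "little")            # IEEE float
  writeBin(1L, con, 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * 4), con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little")
  writeBin(32L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, 4, endian = "little")
  writeBin(audio, con, size = 4, endian = "little")
  invisible(path)
}
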
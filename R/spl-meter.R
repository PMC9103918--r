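#' Sound-level meter state
#'
#' Exponential ("fast", tau = 125 ms by default) time weighting of the squared
#' signal, read out in dB re digital full scale plus a user calibration
#' offset. The state carries the running time-weighted mean square across
#' frames so a stream can be metered frame by frame.
#'
#' @param tau_s Time-weighting constant in seconds (0.125 = "fast").
#' @param floor_db Lowest reportable level in dB; readings are clamped here
#'   (log of zero is undefined).
#' @return An object of class `wdrc_spl_state`.
#' @export
spl_state <- function(tau_s = 0.125, floor_db = -120) {
  if (tau_s <= 0) abort("`tau_s` must be positive.", class = "wdrcnr_invalid_input")
  structure(list(tau_s = tau_s, floor_db = floor_db, mean_square = 0),
            class = "wdrc_spl_state")
}

# one-pole exponential mean-square trace; init = previous running value
ms_trace <- function(x, fs, tau_s, init = 0) {
  a <- exp(-1 / (fs * tau_s))
  as.numeric(stats::filter((1 - a) * x^2, a, method = "recursive", init = init))
}

#' Meter one frame of audio
#'
#' Feeds a frame of normalized samples through the exponential mean-square
#' recursion and returns the frame's average time-weighted level:
#' `10*log10(mean square) + calibration`, clamped at the meter floor.
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\].
#' @param state A [spl_state()]; the returned state carries the running level
#'   into the next frame.
#' @param fs Sampling rate in Hz.
#' @param calibration_offset_db Calibration offset in dB added to the
#'   dB-re-full-scale reading.
#' @return List with `spl_db` (scalar reading) and `state` (updated).
#' @export
spl_frame <- function(samples, state, fs, calibration_offset_db = 0) {
  stopifnot(inherits(state, "wdrc_spl_state"))
  if (length(samples) == 0L) {
    abort("Empty frame.", class = "wdrcnr_invalid_input")
  }
  if (!all(is.finite(samples))) {
    abort("Frame contains non-finite samples.", class = "wdrcnr_invalid_input")
  }
  trace <- ms_trace(samples, fs, state$tau_s, init = state$mean_square)
  state$mean_square <- trace[length(trace)]
  reading <- mean_square_db(mean(trace), state$floor_db) + calibration_offset_db
  list(spl_db = max(reading, state$floor_db), state = state)
}

mean_square_db <- function(ms, floor_db = -120) {
  ifelse(ms > 0, 10 * log10(ms), floor_db)
}

#' Per-frame meter readings over a whole signal
#'
#' Runs the meter once over the stream and reports, for each analysis frame,
#' the average time-weighted level across the frame's span. This is the
#' reading the engine's selector consumes.
#'
#' @param audio Numeric signal.
#' @param cfg An [engine_config()]; uses its frame length, overlap, sampling
#'   rate, calibration offset, time weighting, and (optionally) A-weighting.
#' @return Numeric vector with one reading per frame (see [n_frames()]).
#' @export
spl_track <- function(audio, cfg = engine_config()) {
  n <- length(audio)
  frame_len <- cfg$frame_len
  hop <- frame_hop(cfg)
  if (n < frame_len) {
    abort("Signal shorter than one frame.", class = "wdrcnr_invalid_input")
  }
  if (cfg$a_weighting) audio <- apply_a_weighting(audio, cfg$sample_rate_hz)
  trace <- ms_trace(audio, cfg$sample_rate_hz, cfg$spl_tau_s)
  nf <- n_frames(n, cfg)
  starts <- (seq_len(nf) - 1L) * hop + 1L
  vapply(starts, function(s) {
    e <- min(s + frame_len - 1L, n)
    pmax(mean_square_db(mean(trace[s:e])) + cfg$calibration_offset_db, -120)
  }, numeric(1))
}

#' Settled meter reading of a signal
#'
#' The time-average (in dB) of the per-sample meter trace after an initial
#' settling interval; the reference reading used when scaling synthetic
#' material to a target SPL.
#'
#' @inheritParams spl_frame
#' @param audio Numeric signal.
#' @param settle_s Initial interval, in seconds, excluded from the average.
#' @param tau_s Meter time constant in seconds.
#' @param a_weighting Apply A-frequency weighting before metering.
#' @export
spl_settled <- function(audio, fs, calibration_offset_db = 0,
                        tau_s = 0.125, settle_s = 0.5, a_weighting = FALSE) {
  n <- length(audio)
  skip <- min(n - 1L, round(settle_s * fs))
  if (n < 2L) abort("Signal too short to settle.", class = "wdrcnr_invalid_input")
  if (a_weighting) audio <- apply_a_weighting(audio, fs)
  trace <- ms_trace(audio, fs, tau_s)[(skip + 1L):n]
  trace <- trace[trace > 0]
  if (!length(trace)) return(-120)
  mean(10 * log10(trace)) + calibration_offset_db
}

# Standard A-weighting curve realized as a bilinear-transformed analog filter.
apply_a_weighting <- function(x, fs) {
  f1 <- 20.598997; f2 <- 107.65265; f3 <- 737.86223; f4 <- 12194.217
  poles <- -2 * pi * c(f1, f1, f2, f3, f4, f4)
  zeros <- rep(0, 4)
  # normalize to unity gain at 1 kHz
  s <- 2i * pi * 1000
  g <- 1 / abs(prod(s - zeros) / prod(s - poles))
  dig <- signal::bilinear(zeros, poles, g, fs)
  as.numeric(signal::filter(dig$b, dig$a, x))
}
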
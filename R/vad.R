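#' Voice-activity-detector state
#'
#' A statistical likelihood-ratio detector: each frame's zero-padded
#' periodogram is compared against a running noise power-spectral-density
#' model. Per bin, the a-posteriori SNR and a decision-directed a-priori SNR
#' feed the Gaussian log-likelihood ratio; the geometric mean over bins gives
#' a frame likelihood ratio `L`, reported as a speech-presence probability
#' `p = L / (1 + L)`. The noise PSD adapts by exponential smoothing only on
#' frames judged noise, so speech does not leak into the noise model.
#'
#' @param noise_psd Non-negative numeric vector: noise PSD over the
#'   `fft_len/2 + 1` non-redundant bins, e.g. from [init_noise_model()].
#' @param frame_len Analysis frame length in samples; the FFT length is
#'   `2 * frame_len` (zero-padded).
#' @param alpha_snr Decision-directed smoothing factor for the a-priori SNR.
#' @param alpha_noise Exponential smoothing factor of the noise PSD update.
#' @param vad_threshold Probability at or above which a frame counts as
#'   speech (also gates the noise-PSD update).
#' @param fs Sampling rate in Hz, used to locate the speech band.
#' @param speech_band_hz Frequency interval over which the log-likelihood
#'   ratio is averaged. Speech carries essentially no energy outside
#'   100--4000 Hz, and averaging the LR over the full half-spectrum at a
#'   48 kHz rate would dilute the statistic with hundreds of noise-only
#'   bins.
#' @param xi_min Minimum a-priori SNR (linear) assumed under the speech
#'   hypothesis. Flooring `xi` here makes the detector a generalized
#'   likelihood-ratio test against "speech at least this strong": without it
#'   the decision-directed `xi` collapses to zero on sustained noise and the
#'   log-likelihood ratio degenerates to zero, leaving the probability
#'   pinned at 1/2. The default, 2 (about 3 dB per bin, the minimum
#'   detectable per-bin SNR), puts the expected noise-frame log-LR at about
#'   -0.43 per bin -- roughly three standard deviations of the band-averaged
#'   statistic below the decision point.
#' @return An object of class `wdrc_vad_state`.
#' @export
vad_state <- function(noise_psd, frame_len = 256L, alpha_snr = 0.98,
                      alpha_noise = 0.95, vad_threshold = 0.5, xi_min = 2,
                      fs = 48000, speech_band_hz = c(100, 4000)) {
  if (any(noise_psd < 0)) {
    abort("Noise PSD entries must be non-negative.", class = "wdrcnr_invalid_input")
  }
  if (alpha_snr <= 0 || alpha_snr >= 1 || alpha_noise <= 0 || alpha_noise >= 1) {
    abort("Smoothing factors must lie in (0, 1).", class = "wdrcnr_invalid_input")
  }
  nbins <- as.integer(frame_len) + 1L  # fft_len/2 + 1 with fft_len = 2*frame_len
  if (length(noise_psd) != nbins) {
    abort(sprintf("Noise PSD must have fft_len/2 + 1 = %d bins, got %d.",
                  nbins, length(noise_psd)),
          class = "wdrcnr_invalid_input")
  }
  freq <- (seq_len(nbins) - 1) * fs / (2 * frame_len)
  band_bins <- which(freq >= speech_band_hz[1] & freq <= speech_band_hz[2])
  structure(list(noise_psd = as.numeric(noise_psd),
                 frame_len = as.integer(frame_len),
                 fft_len = 2L * as.integer(frame_len),
                 alpha_snr = alpha_snr, alpha_noise = alpha_noise,
                 vad_threshold = vad_threshold, xi_min = xi_min,
                 band_bins = band_bins,
                 xi_memory = NULL, frames_initialized = 0L),
            class = "wdrc_vad_state")
}

# One-sided periodogram of a frame, zero-padded to fft_len; scaled so white
# noise of variance sigma^2 has expectation sigma^2 per bin.
frame_periodogram <- function(frame, fft_len) {
  n <- length(frame)
  X <- fft(c(frame, numeric(fft_len - n)))
  (Mod(X)[1:(fft_len %/% 2L + 1L)])^2 / n
}

#' Initialize the noise model from lead-in frames
#'
#' The capture protocol records a few seconds of environment noise before any
#' speech; the average periodogram of those frames seeds the noise PSD.
#'
#' @param lead_in_frames A list of numeric frames (equal length), or a matrix
#'   with one frame per column.
#' @inheritParams vad_state
#' @param ... Passed on to [vad_state()].
#' @return A `wdrc_vad_state` whose `noise_psd` is the average lead-in
#'   periodogram.
#' @export
init_noise_model <- function(lead_in_frames, ...) {
  if (is.matrix(lead_in_frames)) {
    lead_in_frames <- lapply(seq_len(ncol(lead_in_frames)),
                             function(j) lead_in_frames[, j])
  }
  if (!length(lead_in_frames)) {
    abort("Need at least one lead-in frame.", class = "wdrcnr_invalid_input")
  }
  frame_len <- length(lead_in_frames[[1]])
  fft_len <- 2L * frame_len
  psds <- vapply(lead_in_frames, frame_periodogram, numeric(frame_len + 1L),
                 fft_len = fft_len)
  st <- vad_state(noise_psd = rowMeans(psds), frame_len = frame_len, ...)
  st$frames_initialized <- length(lead_in_frames)
  st
}

# Core likelihood-ratio scorer on a one-sided power spectrum. Returns the
# speech-presence probability plus updated state. Used by both the public
# per-frame API and the engine (which computes its own spectra).
vad_score_spectrum <- function(psd, state) {
  eps <- 1e-12
  if (sum(psd) <= eps) {   # zero-energy frame cannot contain speech
    return(list(p = 0, state = state))
  }
  noise <- pmax(state$noise_psd, eps)
  gamma <- psd / noise
  if (is.null(state$xi_memory)) state$xi_memory <- rep(1, length(psd))
  xi <- pmax(state$alpha_snr * state$xi_memory +
               (1 - state$alpha_snr) * pmax(gamma - 1, 0), state$xi_min)
  log_lr <- gamma * xi / (1 + xi) - log1p(xi)
  L <- exp(mean(log_lr[state$band_bins]))
  p <- if (is.infinite(L)) 1 else L / (1 + L)
  gain <- xi / (1 + xi)
  state$xi_memory <- gain^2 * gamma
  if (p < state$vad_threshold) {
    state$noise_psd <- state$alpha_noise * state$noise_psd +
      (1 - state$alpha_noise) * psd
  }
  list(p = p, state = state)
}

#' Speech-presence probability of a frame
#'
#' @param frame Numeric frame of `state$frame_len` samples.
#' @param state A `wdrc_vad_state` from [init_noise_model()] or
#'   [vad_state()].
#' @return List with `p` (probability in \[0, 1\]) and `state` (updated:
#'   decision-directed memory always; noise PSD only when the frame scored
#'   below the speech threshold).
#' @export
vad_probability <- function(frame, state) {
  if (!inherits(state, "wdrc_vad_state")) {
    abort("VAD state not initialized; call init_noise_model() first.",
          class = "wdrcnr_state_error")
  }
  if (length(frame) != state$frame_len) {
    abort(sprintf("Frame must have %d samples.", state$frame_len),
          class = "wdrcnr_invalid_input")
  }
  vad_score_spectrum(frame_periodogram(frame, state$fft_len), state)
}

#' Threshold a speech-presence probability
#'
#' A probability at or above the configured threshold counts as speech (ties
#' count as speech: the conservative choice for intelligibility).
#'
#' @param p Probability in \[0, 1\].
#' @param cfg An [engine_config()].
#' @return Logical.
#' @export
is_speech <- function(p, cfg = engine_config()) {
  stopifnot(all(p >= 0 & p <= 1))
  p >= cfg$vad_threshold
}
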
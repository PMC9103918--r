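#' Wiener suppression gain
#'
#' The per-bin Wiener gain `xi / (1 + xi)` for a-priori SNR `xi`, floored to
#' avoid musical noise (a floor of 0.1 caps suppression at -20 dB per bin).
#'
#' @param xi Non-negative a-priori SNR(s), linear scale.
#' @param gain_floor Lower bound on the gain, in (0, 1].
#' @return Gain(s) in \[`gain_floor`, 1\].
#' @export
wiener_gain <- function(xi, gain_floor = 0.1) {
  if (any(xi < 0)) abort("`xi` must be non-negative.", class = "wdrcnr_invalid_input")
  pmax(gain_floor, xi / (1 + xi))
}

#' Noise-reduction state
#'
#' Decision-directed Wiener noise reduction sharing one noise PSD model with
#' the voice activity detector: per STFT bin, the a-priori SNR is the
#' smoothed combination of the previous frame's cleaned SNR and the current
#' instantaneous SNR, and the Wiener gain of each bin is floored. The noise
#' PSD adapts only while the detector judges the frame noise.
#'
#' @inheritParams vad_state
#' @param prior_snr_smoothing Decision-directed smoothing factor.
#' @param gain_floor Per-bin minimum gain in (0, 1].
#' @return An object of class `wdrc_nr_state`.
#' @export
nr_state <- function(noise_psd, frame_len = 256L, prior_snr_smoothing = 0.98,
                     alpha_noise = 0.95, gain_floor = 0.1,
                     vad_threshold = 0.5) {
  if (gain_floor <= 0 || gain_floor > 1) {
    abort("`gain_floor` must lie in (0, 1].", class = "wdrcnr_invalid_input")
  }
  if (length(noise_psd) != frame_len + 1L) {
    abort(sprintf("Noise PSD must have %d bins.", frame_len + 1L),
          class = "wdrcnr_state_error")
  }
  if (any(noise_psd < 0)) {
    abort("Noise PSD entries must be non-negative.", class = "wdrcnr_invalid_input")
  }
  structure(list(noise_psd = as.numeric(noise_psd),
                 frame_len = as.integer(frame_len),
                 fft_len = 2L * as.integer(frame_len),
                 prior_snr_smoothing = prior_snr_smoothing,
                 alpha_noise = alpha_noise, gain_floor = gain_floor,
                 vad_threshold = vad_threshold, xi_memory = NULL),
            class = "wdrc_nr_state")
}

# Per-bin suppression gains for a one-sided power spectrum; updates the
# decision-directed memory and, on noise frames, the noise PSD.
nr_gains_spectrum <- function(psd, state, vad_p) {
  eps <- 1e-12
  noise <- pmax(state$noise_psd, eps)
  gamma <- psd / noise
  if (is.null(state$xi_memory)) state$xi_memory <- rep(1, length(psd))
  a <- state$prior_snr_smoothing
  xi <- a * state$xi_memory + (1 - a) * pmax(gamma - 1, 0)
  g <- wiener_gain(xi, state$gain_floor)
  state$xi_memory <- g^2 * gamma
  if (vad_p < state$vad_threshold) {
    state$noise_psd <- state$alpha_noise * state$noise_psd +
      (1 - state$alpha_noise) * psd
  }
  list(gains = g, state = state)
}

#' Denoise one frame
#'
#' Transforms the frame (zero-padded FFT of length `2 * frame_len`), applies
#' the per-bin floored Wiener gains as a zero-phase spectral weighting, and
#' transforms back. The noise PSD adapts only when `vad_p` falls below the
#' speech threshold.
#'
#' @param frame Numeric frame of `state$frame_len` samples.
#' @param state A [nr_state()] with an initialized noise PSD.
#' @param vad_p Speech-presence probability of this frame.
#' @return List with `frame` (filtered, same length) and `state` (updated).
#' @export
denoise_frame <- function(frame, state, vad_p) {
  if (!inherits(state, "wdrc_nr_state")) {
    abort("NR state not initialized.", class = "wdrcnr_state_error")
  }
  n <- length(frame)
  if (n != state$frame_len) {
    abort(sprintf("Frame must have %d samples.", state$frame_len),
          class = "wdrcnr_invalid_input")
  }
  psd <- frame_periodogram(frame, state$fft_len)
  res <- nr_gains_spectrum(psd, state, vad_p)
  X <- fft(c(frame, numeric(state$fft_len - n)))
  G <- c(res$gains, rev(res$gains[2:state$frame_len]))  # even symmetry
  y <- Re(fft(X * G, inverse = TRUE)) / state$fft_len
  list(frame = y[1:n], state = res$state)
}
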
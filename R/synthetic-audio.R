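#' Synthetic scene recipe
#'
#' Describes a test scene following the field-capture protocol: a noise-only
#' lead-in of a few seconds (so the chain can learn the initial noise
#' conditions) followed by speech mixed over the continuing noise. SPLs are
#' defined against the package's own meter under the synthetic calibration
#' convention (+100 dB offset, i.e. -40 dBFS reads 60 dB SPL).
#'
#' @param noise_kind One of `"white"`, `"pink"`, `"babble_like"`,
#'   `"fan_like"`.
#' @param noise_spl_db,speech_spl_db Target settled SPLs of the noise bed and
#'   the speech component, in dB.
#' @param lead_in_s,speech_s Segment durations in seconds.
#' @param seed Integer seed; every generator is deterministic given it.
#' @return An object of class `wdrc_scene_spec`.
#' @export
scene_spec <- function(noise_kind = "white", noise_spl_db = 60,
                       speech_spl_db = 65, lead_in_s = 3, speech_s = 5,
                       seed = 1L) {
  noise_kind <- match.arg(noise_kind,
                          c("white", "pink", "babble_like", "fan_like"))
  if (lead_in_s <= 0 || speech_s <= 0) {
    abort("Durations must be positive.", class = "wdrcnr_invalid_input")
  }
  if (!is.finite(noise_spl_db) || !is.finite(speech_spl_db)) {
    abort("SPLs must be finite.", class = "wdrcnr_invalid_input")
  }
  structure(list(noise_kind = noise_kind, noise_spl_db = noise_spl_db,
                 speech_spl_db = speech_spl_db, lead_in_s = lead_in_s,
                 speech_s = speech_s, seed = as.integer(seed)),
            class = "wdrc_scene_spec")
}

#' Generate a noise bed
#'
#' `white` is Gaussian; `pink` applies -3 dB/octave spectral shaping;
#' `fan_like` is low-pass-weighted noise with a low-frequency hum (machinery
#' character, most energy below 1 kHz); `babble_like` sums eight independent
#' speech surrogates.
#'
#' @param kind Noise kind (see [scene_spec()]).
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @return Numeric signal with unit RMS.
#' @export
gen_noise <- function(kind, duration_s, fs = 48000, seed = 1L) {
  kind <- match.arg(kind, c("white", "pink", "babble_like", "fan_like"))
  n <- round(duration_s * fs)
  set.seed(seed)
  x <- switch(kind,
    white = rnorm(n),
    pink = {
      w <- rnorm(n)
      k <- 0:(n - 1)
      f <- pmin(k, n - k) * fs / n           # two-sided bin frequencies
      shape <- 1 / sqrt(pmax(f, 20))         # -3 dB/octave, flat below 20 Hz
      shape[1] <- 0
      Re(fft(fft(w) * shape, inverse = TRUE)) / n
    },
    fan_like = {
      a <- exp(-2 * pi * 200 / fs)           # one-pole low-pass, ~200 Hz
      lp <- as.numeric(stats::filter((1 - a) * rnorm(n), a, method = "recursive"))
      t <- (0:(n - 1)) / fs
      hum <- sin(2 * pi * 120 * t + runif(1, 0, 2 * pi)) +
        0.4 * sin(2 * pi * 240 * t + runif(1, 0, 2 * pi))
      lp / stats::sd(lp) + 0.5 * hum
    },
    babble_like = {
      talkers <- lapply(1:8, function(k) {
        sp <- speech_surrogate_spec(f0_hz = 90 + 17 * k,
                                    modulation_rate_hz = 2.5 + 0.45 * k)
        gen_speech_surrogate(duration_s, fs, sp, seed = seed * 100L + k)
      })
      Reduce(`+`, talkers)
    })
  x / stats::sd(x)
}

#' Speech-surrogate recipe
#'
#' A harmonic complex standing in for recorded speech: fundamental near
#' `f0_hz` with slow +/-10% drift, a -6 dB/octave spectral tilt shaped by
#' three formant-like resonances (500/1500/2500 Hz), band-limited below
#' ~4 kHz, and amplitude-modulated at syllabic rate. The modulator is a
#' clipped raised cosine whose voiced fraction per cycle is ~0.7 (the duty
#' cycle), riding on an envelope floor of 0.3 so modulation depth is 0.7.
#'
#' @param f0_hz Nominal fundamental in Hz.
#' @param n_harmonics Number of harmonics.
#' @param modulation_rate_hz Syllabic modulation rate in Hz.
#' @return An object of class `wdrc_speech_spec`.
#' @export
speech_surrogate_spec <- function(f0_hz = 120, n_harmonics = 30L,
                                  modulation_rate_hz = 4) {
  structure(list(f0_hz = f0_hz, n_harmonics = as.integer(n_harmonics),
                 modulation_rate_hz = modulation_rate_hz),
            class = "wdrc_speech_spec")
}

#' Generate a speech surrogate
#'
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param spec A [speech_surrogate_spec()].
#' @param seed Integer seed.
#' @return Numeric signal with unit RMS.
#' @export
gen_speech_surrogate <- function(duration_s, fs = 48000,
                                 spec = speech_surrogate_spec(), seed = 1L) {
  n <- round(duration_s * fs)
  t <- (0:(n - 1)) / fs
  set.seed(seed)
  drift <- 0.6 * sin(2 * pi * 0.4 * t + runif(1, 0, 2 * pi)) +
    0.4 * sin(2 * pi * 0.9 * t + runif(1, 0, 2 * pi))
  f0 <- spec$f0_hz * (1 + 0.1 * drift)
  phase <- 2 * pi * cumsum(f0) / fs
  formant <- function(f) {
    1 + Reduce(`+`, lapply(c(500, 1500, 2500), function(fc) {
      exp(-(log(f / fc))^2 / (2 * 0.2^2))
    }))
  }
  x <- numeric(n)
  for (h in seq_len(spec$n_harmonics)) {
    fh <- h * spec$f0_hz
    if (fh * 1.1 >= fs / 2) break
    amp <- (1 / h) * formant(fh) / (1 + (fh / 3500)^4)
    x <- x + amp * cos(h * phase + runif(1, 0, 2 * pi))
  }
  m <- pmax(0, (cos(2 * pi * spec$modulation_rate_hz * t +
                      runif(1, 0, 2 * pi)) + 0.6) / 1.6)
  env <- 0.3 + 0.7 * m
  y <- env * x
  y / stats::sd(y)
}

#' Scale audio to a target settled SPL
#'
#' Scales the signal so the meter's settled reading (see [spl_settled()])
#' equals the target, under the given calibration. Self-consistent with the
#' package's own meter rather than physically absolute.
#'
#' @param audio Numeric signal (non-silent).
#' @param target_db Target settled SPL in dB.
#' @param calibration_offset_db Calibration offset in dB (synthetic
#'   convention: 100).
#' @param fs Sampling rate in Hz.
#' @return The scaled signal.
#' @export
set_spl <- function(audio, target_db, calibration_offset_db = 100, fs = 48000) {
  if (!length(audio) || all(audio == 0)) {
    abort("Cannot set the SPL of silent audio.", class = "wdrcnr_invalid_input")
  }
  r <- spl_settled(audio, fs, calibration_offset_db)
  audio * 10^((target_db - r) / 20)
}

#' Generate a full synthetic scene
#'
#' Noise-only lead-in at the noise SPL, then the speech surrogate at the
#' speech SPL mixed over the continuing noise bed. Labels are exact by
#' construction: one `"noise"`/`"speech"` tag per sample, the speech segment
#' labelled from its first to last sample.
#'
#' @param spec A [scene_spec()].
#' @param fs Sampling rate in Hz.
#' @return An object of class `wdrc_scene`: `audio`, `labels` (character,
#'   per sample), `fs`, `spec`.
#' @export
gen_scene <- function(spec, fs = 48000) {
  stopifnot(inherits(spec, "wdrc_scene_spec"))
  n1 <- round(spec$lead_in_s * fs)
  n2 <- round(spec$speech_s * fs)
  noise <- gen_noise(spec$noise_kind, spec$lead_in_s + spec$speech_s, fs,
                     seed = spec$seed)
  noise <- set_spl(noise, spec$noise_spl_db, fs = fs)
  speech <- gen_speech_surrogate(spec$speech_s, fs, seed = spec$seed + 1L)
  speech <- set_spl(speech, spec$speech_spl_db, fs = fs)
  audio <- noise
  audio[(n1 + 1):(n1 + n2)] <- audio[(n1 + 1):(n1 + n2)] + speech
  structure(list(audio = audio,
                 labels = rep(c("noise", "speech"), c(n1, n2)),
                 fs = fs, spec = spec),
            class = "wdrc_scene")
}

#' Engine calibration matching a scene's synthetic SPL scale
#'
#' The engine peak-normalizes its input, which shifts digital levels by
#' `20*log10(peak_target / peak)`. This helper returns the calibration offset
#' that compensates, so post-normalization meter readings sit on the scene's
#' synthetic SPL scale -- mirroring the calibrate-against-a-meter workflow of
#' the reference app.
#'
#' @param audio The scene audio as generated.
#' @param base_calibration_db The synthetic calibration convention (100 dB).
#' @param peak The engine's normalization target peak.
#' @return Calibration offset in dB for [engine_config()].
#' @export
scene_calibration_db <- function(audio, base_calibration_db = 100,
                                 peak = 0.95) {
  base_calibration_db - 20 * log10(peak / max(abs(audio)))
}
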
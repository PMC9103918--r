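frame_hop <- function(cfg) {
  as.integer(round(cfg$frame_len * (1 - cfg$overlap_fraction)))
}

#' Number of analysis frames covering a signal
#'
#' `ceiling((n - frame_len) / hop) + 1` frames of `frame_len` samples at hop
#' `frame_len * (1 - overlap_fraction)`; the final frame is zero-padded.
#'
#' @param n Signal length in samples.
#' @param cfg An [engine_config()].
#' @return Integer frame count.
#' @export
n_frames <- function(n, cfg = engine_config()) {
  hop <- frame_hop(cfg)
  if (n < cfg$frame_len) {
    abort("Signal shorter than one frame.", class = "wdrcnr_invalid_input")
  }
  as.integer(ceiling((n - cfg$frame_len) / hop) + 1L)
}

# periodic Hann; its square overlap-adds to a constant at 50% hop
sqrt_hann <- function(n) {
  sqrt(0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n))
}

#' Peak-normalize audio
#'
#' Scales the signal so its peak absolute amplitude is 0.95, making the
#' processing chain's digital levels independent of the capture device's
#' recording gain. Silent input is returned unchanged with a warning.
#'
#' @param audio Numeric signal.
#' @param peak Target peak amplitude.
#' @return List with `audio` (scaled) and `scale` (the factor applied).
#' @export
normalize_audio <- function(audio, peak = 0.95) {
  if (!length(audio)) abort("Empty audio.", class = "wdrcnr_invalid_input")
  pk <- max(abs(audio))
  if (pk == 0) {
    warn("Silent input; normalization skipped.")
    return(list(audio = audio, scale = 1))
  }
  scale <- peak / pk
  list(audio = audio * scale, scale = scale)
}

#' Closed-form algorithmic latency
#'
#' Input-to-output delay of the chain: the double-buffered frame delay
#' (`2 * frame_len / fs`) plus the linear-phase FIR group delay
#' (`order/2 / fs`). Filter crossfades blend concurrent outputs and add no
#' buffering delay.
#'
#' @param cfg An [engine_config()].
#' @param filter_order FIR order; defaults to the configured order.
#' @return Latency in milliseconds.
#' @export
algorithmic_latency_ms <- function(cfg = engine_config(),
                                   filter_order = cfg$fir_order) {
  (2 * cfg$frame_len + filter_order / 2) / cfg$sample_rate_hz * 1000
}

#' Run the full processing chain on a signal
#'
#' Streams the signal through overlapping square-root-Hann frames. Each frame
#' is metered (SPL, smoothed by the attack/release smoother) and scored by
#' the voice activity detector; the flag-update rule makes a temporary filter
#' selection per frame, and every `decision_rate_frames` frames a majority
#' vote over the buffered selections fixes the active filter for the next
#' window (Filter 3, moderate/NR-off, before the first vote). The active
#' filter's magnitude response is applied per frame as a zero-phase spectral
#' weighting -- in series with the adaptive Wiener stage when its NR flag is
#' on -- and the output is rebuilt by overlap-add, trimmed to the input
#' length, and hard-limited at +/-1.
#'
#' @param audio Numeric signal at `cfg$sample_rate_hz`.
#' @param cfg An [engine_config()].
#' @param params A [compression_params()].
#' @param ag An [audiogram()].
#' @param force_filter_index Optional integer 1..6: bypass selection and run
#'   the whole signal through one filter (diagnostic mode).
#' @return An object of class `wdrc_result`: `audio` (processed, same
#'   length), `logs` (tibble: `frame_index`, `vad_prob`, `spl_db`,
#'   `filter_index`), `votes` (tibble of decision boundaries), `scale`
#'   (normalization factor), `limited_samples` (count clamped by the
#'   limiter), plus the configuration and designed bank.
#' @export
process <- function(audio, cfg = engine_config(),
                    params = default_compression_params(),
                    ag = default_audiogram(),
                    force_filter_index = NULL) {
  frame_len <- cfg$frame_len
  hop <- frame_hop(cfg)
  fs <- cfg$sample_rate_hz
  if (length(audio) < frame_len + hop) {
    abort("Input too short: need at least one full frame plus a hop.",
          class = "wdrcnr_invalid_input")
  }
  if (!all(is.finite(audio))) {
    abort("Input contains non-finite samples.", class = "wdrcnr_invalid_input")
  }

  scale <- 1
  if (cfg$normalize) {
    nz <- normalize_audio(audio)
    audio <- nz$audio
    scale <- nz$scale
  }
  n <- length(audio)
  nf <- n_frames(n, cfg)

  mapped <- map_bands(ag)
  bank <- design_filter_bank(params, mapped$plan, cfg)
  fft_len <- 2L * frame_len
  nbins <- frame_len + 1L
  # zero-phase per-bin gains realized by each designed FIR
  bank_gains <- lapply(bank, function(f) {
    Mod(fft(c(f$coefficients, numeric(fft_len - length(f$coefficients)))))[1:nbins]
  })
  nr_on <- vapply(bank, function(f) f$nr_enabled, logical(1))

  w <- sqrt_hann(frame_len)
  wpow <- sum(w^2)

  spl_raw <- spl_track(audio, cfg)
  spl_sm <- smooth_level(spl_raw, smoother(params$attack_s, params$release_s),
                         hop / fs)$smoothed_db

  init_n <- min(cfg$noise_init_frames, nf)
  vad_st <- NULL
  nr_st <- NULL
  psd_accum <- numeric(nbins)

  flags <- flag_state("moderate", "off")
  active <- if (is.null(force_filter_index)) 3L else as.integer(force_filter_index)
  if (active < 1L || active > 6L) {
    abort("`force_filter_index` must be in 1..6.", class = "wdrcnr_invalid_input")
  }
  buffer <- integer(0)
  n_x <- max(1L, as.integer(ceiling(cfg$crossfade_s * fs / hop)))
  xfade_left <- 0L
  g_prev <- NULL

  ola <- numeric(n + fft_len)
  wsum <- numeric(n + fft_len)
  vad_p <- numeric(nf)
  filt_idx <- integer(nf)
  votes <- integer(0)
  vote_frames <- integer(0)

  for (i in seq_len(nf)) {
    s <- (i - 1L) * hop + 1L
    e <- min(s + frame_len - 1L, n)
    x <- numeric(frame_len)
    x[1:(e - s + 1L)] <- audio[s:e]
    X <- fft(c(x * w, numeric(frame_len)))
    psd <- (Mod(X)[1:nbins])^2 / wpow

    if (i <= init_n) {
      psd_accum <- psd_accum + psd
      p <- 0
      if (i == init_n) {
        psd0 <- psd_accum / init_n
        vad_st <- vad_state(psd0, frame_len, vad_threshold = cfg$vad_threshold)
        nr_st <- nr_state(psd0, frame_len, gain_floor = cfg$nr_gain_floor,
                          vad_threshold = cfg$vad_threshold)
      }
      nr_g <- rep(1, nbins)
    } else {
      sc <- vad_score_spectrum(psd, vad_st)
      p <- sc$p
      vad_st <- sc$state
      ng <- nr_gains_spectrum(psd, nr_st, p)
      nr_g <- ng$gains
      nr_st <- ng$state
    }
    vad_p[i] <- p
    filt_idx[i] <- active

    # synthesize with the filter active during this frame
    gf <- bank_gains[[active]]
    if (xfade_left > 0L) {
      t_blend <- 1 - xfade_left / n_x
      gf <- (1 - t_blend) * g_prev + t_blend * gf
      xfade_left <- xfade_left - 1L
    }
    gtot <- if (nr_on[active]) gf * nr_g else gf
    G <- c(gtot, rev(gtot[2:frame_len]))
    y <- Re(fft(X * G, inverse = TRUE))[1:frame_len] / fft_len
    idx <- s:(s + frame_len - 1L)
    ola[idx] <- ola[idx] + y * w
    wsum[idx] <- wsum[idx] + w^2

    # temporary selection + periodic vote (applies from the next frame on)
    if (is.null(force_filter_index)) {
      sel <- temporary_selection(p, spl_sm[i], flags, cfg)
      flags <- sel$flags
      buffer <- c(buffer, sel$index)
      if (i %% cfg$decision_rate_frames == 0L) {
        winner <- majority_vote(buffer)
        votes <- c(votes, winner)
        vote_frames <- c(vote_frames, i)
        buffer <- integer(0)
        if (winner != active) {
          g_prev <- bank_gains[[active]]
          xfade_left <- n_x
          active <- winner
        }
      }
    }
  }

  out <- numeric(n)
  ok <- wsum[1:n] > 1e-8
  out[ok] <- ola[1:n][ok] / wsum[1:n][ok]
  limited <- sum(abs(out) > 1)
  if (limited > 0) {
    warn(sprintf("Hard limiter engaged on %d samples.", limited))
    out <- pmin(1, pmax(-1, out))
  }

  structure(list(audio = out,
                 logs = tibble(frame_index = seq_len(nf),
                               vad_prob = vad_p,
                               spl_db = spl_sm,
                               filter_index = filt_idx),
                 votes = tibble(frame_index = vote_frames,
                                filter_index = votes),
                 scale = scale,
                 limited_samples = limited,
                 cfg = cfg, params = params, bank = bank),
            class = "wdrc_result")
}

#' Write the per-frame debug log
#'
#' Tab-separated text, one row per frame: `frame_index`, `vad_prob` (3
#' decimals), `spl_db` (1 decimal), `filter_index` -- the same content the
#' reference app stores when its debug option is set.
#'
#' @param result A `wdrc_result` from [process()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_log <- function(result, path) {
  stopifnot(inherits(result, "wdrc_result"))
  lg <- result$logs
  lines <- sprintf("%d\t%.3f\t%.1f\t%d", lg$frame_index, lg$vad_prob,
                   lg$spl_db, lg$filter_index)
  writeLines(c("frame_index\tvad_prob\tspl_db\tfilter_index", lines), path)
  invisible(path)
}
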
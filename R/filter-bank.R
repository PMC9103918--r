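#' Target magnitude of a band-gain prescription
#'
#' Piecewise target in dB over frequency: the gain is held across each
#' processing band and ramps linearly across every internal band edge, the
#' ramp spanning one eighth of each adjacent band. Below the first band the
#' lowest-band gain is held to DC; above the last band the top-band gain is
#' held to Nyquist (the chain does not shape content outside 125--6000 Hz).
#'
#' @param freq_hz Frequencies at which to evaluate, in Hz.
#' @param plan A band plan from [map_bands()].
#' @param gains_db Numeric vector of 5 band gains in dB.
#' @param fs Sampling rate in Hz.
#' @return Target magnitude in dB at `freq_hz`.
#' @keywords internal
fir_target_db <- function(freq_hz, plan, gains_db, fs) {
  edges <- plan$edges_hz
  knots_f <- 0
  knots_g <- gains_db[1]
  for (e in 2:5) {
    bw_lo <- edges[e] - edges[e - 1]
    bw_hi <- edges[e + 1] - edges[e]
    knots_f <- c(knots_f, edges[e] - bw_lo / 8, edges[e] + bw_hi / 8)
    knots_g <- c(knots_g, gains_db[e - 1], gains_db[e])
  }
  knots_f <- c(knots_f, fs / 2)
  knots_g <- c(knots_g, gains_db[5])
  approx(knots_f, knots_g, xout = freq_hz, rule = 2)$y
}

#' Design one selectable filter
#'
#' Linear-phase FIR (frequency-sampling design, even order, symmetric taps)
#' whose magnitude realizes the static per-band compression gains of a speech
#' category; the noise-reduction setting is carried as a routing flag -- when
#' on, the adaptive Wiener stage runs in series with the FIR inside the
#' engine.
#'
#' @param category `"soft"`, `"moderate"` or `"loud"`.
#' @param nr_enabled Logical: is the Wiener stage routed in series.
#' @param params A [compression_params()].
#' @param plan A band plan from [map_bands()].
#' @param cfg An [engine_config()].
#' @return An object of class `wdrc_filter`: `index`, `coefficients`
#'   (`fir_order + 1` symmetric taps), `nr_enabled`, `category`,
#'   `band_gains_db`.
#' @export
design_filter <- function(category, nr_enabled,
                          params = default_compression_params(),
                          plan = map_bands(default_audiogram())$plan,
                          cfg = engine_config()) {
  category <- match.arg(category, wdrc_categories)
  gains_db <- band_gains_db(category, params, cfg = cfg)
  if (any(gains_db > 60)) {
    abort(sprintf("Unachievable band gain (> 60 dB): %.1f dB.", max(gains_db)),
          class = "wdrcnr_design_error")
  }
  # Frequency-sampling design with center-gain correction: at this order the
  # window mainlobe smears adjacent band gains into the low band centers, so
  # the target band gains are iteratively adjusted by the measured error at
  # the centers until the realized response matches the prescription.
  npts <- 513L
  fgrid <- seq(0, 1, length.out = npts)
  adjusted <- gains_db
  for (it in 1:8) {
    mag <- 10^(fir_target_db(fgrid * cfg$sample_rate_hz / 2, plan, adjusted,
                             cfg$sample_rate_hz) / 20)
    h <- as.numeric(signal::fir2(cfg$fir_order, fgrid, mag))
    got <- filter_response_db(list(coefficients = h), plan$centers_hz,
                              fs = cfg$sample_rate_hz)
    err <- got - gains_db
    if (max(abs(err)) < 0.05) break
    adjusted <- adjusted - err
  }
  structure(list(index = filter_index_for(flag_state(category,
                                                     if (nr_enabled) "on" else "off")),
                 coefficients = h, nr_enabled = isTRUE(nr_enabled),
                 category = category, band_gains_db = gains_db),
            class = "wdrc_filter")
}

#' Design the full six-filter bank
#'
#' @inheritParams design_filter
#' @return A list of six `wdrc_filter` objects (class `wdrc_filter_bank`),
#'   ordered by filter index.
#' @export
design_filter_bank <- function(params = default_compression_params(),
                               plan = map_bands(default_audiogram())$plan,
                               cfg = engine_config()) {
  bank <- lapply(1:6, function(i) {
    fl <- flags_for_index(i)
    design_filter(fl$wdrc, fl$nr == "on", params, plan, cfg)
  })
  structure(bank, class = "wdrc_filter_bank")
}

#' Magnitude response of a designed filter
#'
#' @param filt A `wdrc_filter`.
#' @param freq_hz Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @param nfft FFT length used to sample the response.
#' @return Magnitude in dB at `freq_hz`.
#' @export
filter_response_db <- function(filt, freq_hz, fs = 48000, nfft = 65536L) {
  h <- filt$coefficients
  H <- Mod(fft(c(h, numeric(nfft - length(h)))))[1:(nfft %/% 2L)]
  fgrid <- (seq_len(nfft %/% 2L) - 1) * fs / nfft
  20 * log10(pmax(approx(fgrid, H, xout = freq_hz)$y, 1e-12))
}

#' Per-frame temporary filter selection
#'
#' Implements the flag-update rule: a noise-only frame (speech probability
#' below threshold) updates the noise-reduction flag by comparing the frame
#' SPL against the NR activation threshold; a speech frame updates the
#' speech-level flag from the SPL category. The other flag is left unchanged,
#' and the filter index for the updated flag pair is returned.
#'
#' @param vad_p Speech-presence probability of the frame.
#' @param spl_db Frame SPL reading in dB.
#' @param flags Current [flag_state()].
#' @param cfg An [engine_config()].
#' @return List with `index` (1..6) and `flags` (updated).
#' @export
temporary_selection <- function(vad_p, spl_db, flags, cfg = engine_config()) {
  stopifnot(inherits(flags, "wdrc_flag_state"))
  if (is_speech(vad_p, cfg)) {
    flags$wdrc <- classify_speech_level(spl_db, cfg)
  } else {
    flags$nr <- if (spl_db >= cfg$nr_spl_threshold_db) "on" else "off"
  }
  list(index = filter_index_for(flags), flags = flags)
}

#' Majority vote over a decision buffer
#'
#' The most frequent filter index in the buffer wins; ties break toward the
#' lowest index (the less aggressive setting).
#'
#' @param entries Integer vector of filter indices (1..6).
#' @return The winning index.
#' @export
majority_vote <- function(entries) {
  if (!length(entries)) {
    abort("Decision buffer is empty.", class = "wdrcnr_state_error")
  }
  counts <- tabulate(as.integer(entries), nbins = 6L)
  which.max(counts)  # first maximum = lowest index on ties
}

#' Export filter-bank coefficients as plain text
#'
#' Writes one whitespace-separated line of taps per filter, prefixed by the
#' filter index, for external inspection.
#'
#' @param bank A `wdrc_filter_bank`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_filter_bank <- function(bank, path) {
  lines <- vapply(bank, function(f) {
    paste(c(sprintf("# filter %d (%s, NR %s)", f$index, f$category,
                    if (f$nr_enabled) "on" else "off"),
            format(f$coefficients, digits = 17)), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
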
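#' Nine-band audiogram
#'
#' An audiogram records, per frequency band, the lowest sound pressure level
#' (dB SPL) audible to a listener. The compression prescription consumes the
#' nine bands conventionally used for hearing-aid fitting, spanning
#' 125--6000 Hz.
#'
#' @param thresholds_db_spl Numeric vector of 9 hearing thresholds in dB SPL.
#' @param band_edges_hz Numeric vector of 10 strictly increasing band edges in
#'   Hz defining 9 contiguous bands. Defaults to the conventional
#'   125--6000 Hz grid.
#' @return An object of class `wdrc_audiogram`: a list with `band_edges_hz`
#'   and `thresholds_db_spl`.
#' @examples
#' ag <- default_audiogram()
#' map_bands(ag)
#' @export
audiogram <- function(thresholds_db_spl,
                      band_edges_hz = c(125, 250, 500, 750, 1000, 1500,
                                        2000, 3000, 4000, 6000)) {
  if (length(band_edges_hz) != 10L || any(diff(band_edges_hz) <= 0)) {
    abort("`band_edges_hz` must be 10 strictly increasing edges (9 contiguous bands).",
          class = "wdrcnr_config_error")
  }
  if (length(thresholds_db_spl) != 9L) {
    abort(sprintf("An audiogram needs 9 band thresholds, got %d.",
                  length(thresholds_db_spl)),
          class = "wdrcnr_config_error")
  }
  if (!all(is.finite(thresholds_db_spl)) || any(thresholds_db_spl < 0)) {
    abort("Audiogram thresholds must be finite and non-negative (dB SPL).",
          class = "wdrcnr_config_error")
  }
  structure(list(band_edges_hz = as.numeric(band_edges_hz),
                 thresholds_db_spl = as.numeric(thresholds_db_spl)),
            class = "wdrc_audiogram")
}

#' @rdname audiogram
#' @export
default_audiogram <- function() {
  audiogram(c(20, 25, 30, 30, 35, 35, 40, 35, 35))
}

#' Map the nine audiogram bands onto the five processing bands
#'
#' The processing chain runs on five bands to keep the per-frame cost low.
#' The nine prescription bands are merged pairwise --
#' \{125--500\}, \{500--1000\}, \{1000--2000\}, \{2000--4000\}, \{4000--6000\} Hz --
#' and each merged threshold is the arithmetic mean of its constituent
#' thresholds (the top band maps alone).
#'
#' @param ag A [audiogram()] object.
#' @return A list with `plan` (a `wdrc_band_plan`: `edges_hz`, 6 edges for 5
#'   contiguous bands, and `centers_hz`, their geometric-mean centers) and
#'   `thresholds_db_spl` (5 merged thresholds).
#' @export
map_bands <- function(ag) {
  if (!inherits(ag, "wdrc_audiogram")) {
    abort("`ag` must be an audiogram object.", class = "wdrcnr_config_error")
  }
  groups <- list(1:2, 3:4, 5:6, 7:8, 9L)
  edges <- c(ag$band_edges_hz[1],
             vapply(groups, function(g) ag$band_edges_hz[max(g) + 1L], numeric(1)))
  thresholds <- vapply(groups, function(g) mean(ag$thresholds_db_spl[g]), numeric(1))
  plan <- structure(list(edges_hz = edges,
                         centers_hz = sqrt(edges[-6] * edges[-1])),
                    class = "wdrc_band_plan")
  list(plan = plan, thresholds_db_spl = thresholds)
}

#' Per-band compression prescription
#'
#' Compression ratios and makeup gains per speech-intensity category (rows:
#' soft, moderate, loud) and processing band (5 columns), plus the global
#' compressor dynamics. Defaults are the nominal prescription derived from the
#' sample audiogram: unity ratios with large makeup for soft speech, moderate
#' ratios for moderate speech, and strong ratios with small makeup for loud
#' speech; release 1 s, attack 0.01 s, threshold -45 dBFS, knee width 5 dB.
#'
#' @param ratios 3x5 numeric matrix of compression ratios (all >= 1).
#' @param makeup_gains_db 3x5 numeric matrix of makeup gains in dB.
#' @param attack_s,release_s Attack and release time constants in seconds.
#' @param threshold_dbfs Compression threshold in dB re digital full scale.
#' @param knee_db Soft-knee width in dB (>= 0; 0 gives a hard knee).
#' @return An object of class `wdrc_compression_params`.
#' @export
compression_params <- function(ratios, makeup_gains_db,
                               attack_s = 0.01, release_s = 1,
                               threshold_dbfs = -45, knee_db = 5) {
  ratios <- as.matrix(ratios)
  makeup_gains_db <- as.matrix(makeup_gains_db)
  if (!all(dim(ratios) == c(3L, 5L)) || !all(dim(makeup_gains_db) == c(3L, 5L))) {
    abort("`ratios` and `makeup_gains_db` must be 3x5 (soft/moderate/loud x 5 bands).",
          class = "wdrcnr_config_error")
  }
  if (any(ratios < 1)) {
    abort("Compression ratios must be >= 1.", class = "wdrcnr_config_error")
  }
  if (attack_s <= 0 || release_s <= 0 || knee_db < 0) {
    abort("Dynamics must satisfy attack_s > 0, release_s > 0, knee_db >= 0.",
          class = "wdrcnr_config_error")
  }
  rownames(ratios) <- rownames(makeup_gains_db) <- c("soft", "moderate", "loud")
  structure(list(ratios = ratios, makeup_gains_db = makeup_gains_db,
                 attack_s = attack_s, release_s = release_s,
                 threshold_dbfs = threshold_dbfs, knee_db = knee_db),
            class = "wdrc_compression_params")
}

#' @rdname compression_params
#' @export
default_compression_params <- function() {
  compression_params(
    ratios = rbind(c(1.0, 1.0, 1.0, 1.0, 1.0),
                   c(1.6, 2.0, 1.6, 1.6, 5.0),
                   c(3.0, 2.8, 5.0, 20.0, 20.0)),
    makeup_gains_db = rbind(c(10.0, 11.0, 14.0, 25.0, 21.0),
                            c(8.0, 9.0, 13.0, 23.0, 19.0),
                            c(6.0, 4.0, 8.0, 18.0, 15.0))
  )
}

#' Engine configuration
#'
#' All tunable parameters of the processing chain. Defaults reproduce the
#' reference configuration: 48 kHz audio in 256-sample frames with 50%
#' overlap, a decision (majority vote) every 200 frames, speech-level
#' boundaries at 55 and 75 dB SPL, and a noise-reduction activation threshold
#' of 55 dB SPL measured on noise-only frames.
#'
#' @param sample_rate_hz Sampling rate in Hz.
#' @param frame_len Frame length in samples.
#' @param overlap_fraction Fraction of overlap between consecutive frames.
#' @param decision_rate_frames Number of frames aggregated per majority vote.
#' @param vad_threshold Speech-presence probability at or above which a frame
#'   counts as speech.
#' @param soft_upper_db,loud_lower_db Speech-level category boundaries in dB
#'   SPL; readings below `soft_upper_db` are soft, above `loud_lower_db` loud,
#'   and the closed interval between them moderate.
#' @param nr_spl_threshold_db Noise SPL at or above which the noise-reduction
#'   flag turns on (evaluated on noise-only frames).
#' @param calibration_offset_db User calibration added to the meter's
#'   dB-re-full-scale reading so it matches a physical SPL meter.
#' @param seed Integer seed recorded in the configuration (the engine itself
#'   is deterministic; the seed governs synthetic fixtures).
#' @param fir_order FIR filter order for the filter bank (even; `fir_order +
#'   1` symmetric taps).
#' @param nr_gain_floor Lower bound on the per-bin Wiener gain (linear).
#' @param noise_init_frames Number of initial frames used to seed the noise
#'   spectrum model before the detector starts scoring frames.
#' @param crossfade_s Duration of the linear crossfade applied when the active
#'   filter changes.
#' @param representative_levels_dbfs Named numeric vector of the operating
#'   levels (dBFS) at which the static gains of the soft/moderate/loud filters
#'   are evaluated.
#' @param normalize Whether [process()] peak-normalizes the input before
#'   processing.
#' @param spl_tau_s Meter time-weighting constant in seconds ("fast" =
#'   0.125).
#' @param a_weighting Apply A-frequency-weighting in the meter instead of flat
#'   (Z) weighting.
#' @return An object of class `wdrc_engine_config` (a named list).
#' @export
engine_config <- function(sample_rate_hz = 48000L,
                          frame_len = 256L,
                          overlap_fraction = 0.5,
                          decision_rate_frames = 200L,
                          vad_threshold = 0.5,
                          soft_upper_db = 55,
                          loud_lower_db = 75,
                          nr_spl_threshold_db = 55,
                          calibration_offset_db = 0,
                          seed = 1L,
                          fir_order = 128L,
                          nr_gain_floor = 0.1,
                          noise_init_frames = 100L,
                          crossfade_s = 0.010,
                          representative_levels_dbfs = c(soft = -50,
                                                         moderate = -35,
                                                         loud = -20),
                          normalize = TRUE,
                          spl_tau_s = 0.125,
                          a_weighting = FALSE) {
  cfg <- structure(list(sample_rate_hz = as.integer(sample_rate_hz),
                        frame_len = as.integer(frame_len),
                        overlap_fraction = overlap_fraction,
                        decision_rate_frames = as.integer(decision_rate_frames),
                        vad_threshold = vad_threshold,
                        soft_upper_db = soft_upper_db,
                        loud_lower_db = loud_lower_db,
                        nr_spl_threshold_db = nr_spl_threshold_db,
                        calibration_offset_db = calibration_offset_db,
                        seed = as.integer(seed),
                        fir_order = as.integer(fir_order),
                        nr_gain_floor = nr_gain_floor,
                        noise_init_frames = as.integer(noise_init_frames),
                        crossfade_s = crossfade_s,
                        representative_levels_dbfs = representative_levels_dbfs,
                        normalize = isTRUE(normalize),
                        spl_tau_s = spl_tau_s,
                        a_weighting = isTRUE(a_weighting)),
                   class = "wdrc_engine_config")
  validate_engine_config(cfg)
}

validate_engine_config <- function(cfg) {
  if (cfg$sample_rate_hz <= 0 || cfg$frame_len <= 0) {
    abort("Sample rate and frame length must be positive.",
          class = "wdrcnr_config_error")
  }
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction >= 1) {
    abort("`overlap_fraction` must lie in [0, 1).", class = "wdrcnr_config_error")
  }
  if (cfg$decision_rate_frames < 1L) {
    abort("`decision_rate_frames` must be >= 1.", class = "wdrcnr_config_error")
  }
  if (cfg$vad_threshold <= 0 || cfg$vad_threshold >= 1) {
    abort("`vad_threshold` must lie in (0, 1).", class = "wdrcnr_config_error")
  }
  if (cfg$soft_upper_db > cfg$loud_lower_db) {
    abort("`soft_upper_db` must not exceed `loud_lower_db`.",
          class = "wdrcnr_config_error")
  }
  if (cfg$fir_order %% 2L != 0L) {
    abort("`fir_order` must be even (type-I linear phase).",
          class = "wdrcnr_config_error")
  }
  cfg
}

wdrc_categories <- c("soft", "moderate", "loud")

#' Flag state of the selector
#'
#' The selector tracks two flags: the speech-level flag (soft / moderate /
#' loud, updated on speech frames) and the noise-reduction flag (off / on,
#' updated on noise-only frames).
#'
#' @param wdrc One of `"soft"`, `"moderate"`, `"loud"`.
#' @param nr `"off"` or `"on"`.
#' @return An object of class `wdrc_flag_state`.
#' @export
flag_state <- function(wdrc = "moderate", nr = "off") {
  wdrc <- match.arg(wdrc, wdrc_categories)
  nr <- match.arg(nr, c("off", "on"))
  structure(list(wdrc = wdrc, nr = nr), class = "wdrc_flag_state")
}

#' Filter index for a flag combination
#'
#' The six filters are indexed by speech level and noise-reduction setting:
#' (soft, off) -> 1, (soft, on) -> 2, (moderate, off) -> 3, (moderate, on) -> 4,
#' (loud, off) -> 5, (loud, on) -> 6.
#'
#' @param flags A [flag_state()].
#' @return Integer in 1..6.
#' @export
filter_index_for <- function(flags) {
  stopifnot(inherits(flags, "wdrc_flag_state"))
  2L * (match(flags$wdrc, wdrc_categories) - 1L) + ifelse(flags$nr == "on", 2L, 1L)
}

#' Flag combination for a filter index
#'
#' Inverse of [filter_index_for()].
#'
#' @param index Integer in 1..6.
#' @return A [flag_state()].
#' @export
flags_for_index <- function(index) {
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 1L || index > 6L) {
    abort("`index` must be a single integer in 1..6.",
          class = "wdrcnr_invalid_input")
  }
  flag_state(wdrc = wdrc_categories[(index + 1L) %/% 2L],
             nr = if (index %% 2L == 0L) "on" else "off")
}

#' Classify a speech SPL reading into an intensity category
#'
#' Readings below `soft_upper_db` (default 55 dB) are soft, readings above
#' `loud_lower_db` (default 75 dB) are loud, and the closed interval between
#' them is moderate (both boundaries inclusive of moderate).
#'
#' @param spl_db Numeric SPL reading(s) in dB.
#' @param cfg An [engine_config()].
#' @return Character vector of categories.
#' @export
classify_speech_level <- function(spl_db, cfg = engine_config()) {
  if (any(is.na(spl_db)) || any(!is.finite(spl_db))) {
    abort("SPL readings must be finite.", class = "wdrcnr_invalid_input")
  }
  out <- rep("moderate", length(spl_db))
  out[spl_db < cfg$soft_upper_db] <- "soft"
  out[spl_db > cfg$loud_lower_db] <- "loud"
  out
}
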
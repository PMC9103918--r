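# Shared fixtures, built in code at test time.

fs_default <- 48000

# Frames of seeded Gaussian noise for detector tests.
noise_frames <- function(n, sd = 0.01, frame_len = 256L, seed = 42L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) rnorm(frame_len, sd = sd))
}

# A harmonic complex confined to the speech band, unit RMS.
harmonic_frame <- function(frame_len = 256L, f0 = 150, n_harm = 15L,
                           fs = fs_default, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(frame_len) - 1) / fs
  x <- rowSums(vapply(seq_len(n_harm), function(h) {
    cos(2 * pi * h * f0 * t + stats::runif(1, 0, 2 * pi))
  }, numeric(frame_len)))
  x / sqrt(mean(x^2))
}

# Engine configuration matched to a synthetic scene's SPL scale.
scene_engine_config <- function(scene, ...) {
  args <- list(...)
  if (is.null(args$calibration_offset_db)) {
    args$calibration_offset_db <- scene_calibration_db(scene$audio)
  }
  do.call(engine_config, args)
}

# The flag pair a scene was constructed to elicit, as a filter index.
scene_expected_filter <- function(speech_spl_db, noise_spl_db,
                                  cfg = engine_config()) {
  flag_state(classify_speech_level(speech_spl_db, cfg),
             if (noise_spl_db >= cfg$nr_spl_threshold_db) "on" else "off") |>
    filter_index_for()
}

# Majority votes taken over windows that lie fully inside the speech region,
# skipping one settling window after speech onset.
speech_region_votes <- function(result, scene, cfg) {
  hop <- cfg$frame_len * (1 - cfg$overlap_fraction)
  onset_frame <- ceiling(which(scene$labels == "speech")[1] / hop)
  v <- result$votes
  v[v$frame_index - cfg$decision_rate_frames + 1 >
      onset_frame + cfg$decision_rate_frames, ]
}
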
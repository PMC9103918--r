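test_that("noise generators are reproducible and spectrally shaped", {
  a <- gen_noise("white", 0.5, seed = 10L)
  b <- gen_noise("white", 0.5, seed = 10L)
  expect_identical(a, b)
  expect_false(identical(a, gen_noise("white", 0.5, seed = 11L)))

  # pink: slope between -2.5 and -3.5 dB/octave over 100-6000 Hz
  x <- gen_noise("pink", 4, seed = 3L)
  ps <- Mod(fft(x))^2
  f <- (seq_along(ps) - 1) * fs_default / length(ps)
  keep <- f >= 100 & f <= 6000
  fit <- stats::lm(db ~ oct, data.frame(db = 10 * log10(ps[keep]),
                                        oct = log2(f[keep])))
  expect_gt(coef(fit)[2], -3.5)
  expect_lt(coef(fit)[2], -2.5)

  # fan-like: at least 70% of energy below 1 kHz
  y <- gen_noise("fan_like", 2, seed = 6L)
  pf <- Mod(fft(y))^2
  ff <- (seq_along(pf) - 1) * fs_default / length(pf)
  half <- ff <= fs_default / 2
  expect_gt(sum(pf[half & ff < 1000]) / sum(pf[half]), 0.7)
})

test_that("the speech surrogate has the prescribed spectral and temporal form", {
  sp <- gen_speech_surrogate(2, seed = 21L)
  n <- length(sp)
  mag <- Mod(fft(sp))[1:(n / 2)]
  f <- (0:(n / 2 - 1)) * fs_default / n
  # strongest narrowband component at f0 within +/-10%
  peak_f <- f[which.max(mag)]
  expect_gt(peak_f, 120 * 0.9)
  expect_lt(peak_f, 120 * 1.1)
  # energy concentrated in the speech band
  band <- f >= 100 & f <= 4000
  expect_gt(sum(mag[band]^2) / sum(mag^2), 0.95)
  # envelope modulation peaks near the syllabic rate
  env <- ms_env <- stats::filter(sp^2, rep(1 / 480, 480), sides = 2)
  env[is.na(env)] <- mean(env, na.rm = TRUE)
  emag <- Mod(fft(as.numeric(env - mean(env))))[1:(n / 2)]
  mod_f <- f[which.max(emag)]
  expect_gt(mod_f, 2.5)
  expect_lt(mod_f, 5.5)
  # different seeds: different waveforms, similar long-term octave spectra
  sp2 <- gen_speech_surrogate(2, seed = 22L)
  expect_false(identical(sp, sp2))
  octs <- function(x) {
    m <- Mod(fft(x))[1:(length(x) / 2)]^2
    fo <- (0:(length(x) / 2 - 1)) * fs_default / length(x)
    vapply(c(125, 250, 500, 1000, 2000), function(lo) {
      10 * log10(sum(m[fo >= lo & fo < 2 * lo]))
    }, numeric(1))
  }
  expect_lt(max(abs(octs(sp) - octs(sp2))), 3)
})

test_that("set_spl drives the settled meter reading to the target", {
  x <- gen_noise("white", 2, seed = 2L)
  for (target in c(50, 60)) {
    y <- set_spl(x, target)
    expect_equal(spl_settled(y, fs_default, 100), target, tolerance = 0.1)
  }
  y60 <- set_spl(x, 60)
  y70 <- set_spl(x, 70)
  expect_equal(spl_settled(y70, fs_default, 100) -
                 spl_settled(y60, fs_default, 100), 10, tolerance = 0.1)
  expect_error(set_spl(numeric(100), 60), class = "wdrcnr_invalid_input")
})

test_that("scenes assemble lead-in plus mixed speech with exact labels", {
  spec <- scene_spec("white", noise_spl_db = 50, speech_spl_db = 65,
                     lead_in_s = 3, speech_s = 5, seed = 7L)
  sc <- gen_scene(spec)
  expect_length(sc$audio, 8 * fs_default)
  expect_equal(sc$labels[1:(3 * fs_default)], rep("noise", 3 * fs_default))
  expect_equal(unique(sc$labels[(3 * fs_default + 1):(8 * fs_default)]),
               "speech")
  # lead-in segment sits at the noise SPL
  expect_equal(spl_settled(sc$audio[1:(3 * fs_default)], fs_default, 100),
               50, tolerance = 0.2)
  expect_identical(gen_scene(spec)$audio, sc$audio)
})

test_that("frame-level VAD accuracy exceeds 90% on an SNR >= 10 dB scene suite", {
  hits <- total <- 0
  for (seed in 1:3) {
    sc <- gen_scene(scene_spec("white", noise_spl_db = 50,
                               speech_spl_db = 62, lead_in_s = 2,
                               speech_s = 4, seed = seed))
    cfg <- scene_engine_config(sc, normalize = FALSE,
                               calibration_offset_db = 100)
    r <- process(sc$audio, cfg)
    hop <- 128
    frame_label <- sc$labels[pmin((r$logs$frame_index - 1) * hop + 128,
                                  length(sc$labels))]
    decided <- is_speech(r$logs$vad_prob, cfg)
    skip <- r$logs$frame_index <= cfg$noise_init_frames
    hits <- hits + sum((decided == (frame_label == "speech"))[!skip])
    total <- total + sum(!skip)
  }
  expect_gt(hits / total, 0.9)
})

test_that("scene-driven selection respects the NR threshold from ground truth", {
  # quiet noise (40 dB): NR stays off, soft speech -> Filter 1
  sc <- gen_scene(scene_spec("white", noise_spl_db = 40, speech_spl_db = 50,
                             lead_in_s = 2, speech_s = 4, seed = 19L))
  cfg <- scene_engine_config(sc)
  r <- suppressWarnings(process(sc$audio, cfg))
  v <- speech_region_votes(r, sc, cfg)
  expect_true(majority_vote(v$filter_index) %in% c(1L, 2L))
  expect_true(all(r$logs$filter_index %in% c(1L, 3L, 5L)))  # NR never engages
})
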
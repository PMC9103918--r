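test_that("nine-to-five band merge averages thresholds and conserves the span", {
  m <- map_bands(default_audiogram())
  expect_equal(m$thresholds_db_spl, c(22.5, 30, 35, 37.5, 35))
  expect_equal(m$plan$edges_hz, c(125, 500, 1000, 2000, 4000, 6000))
  expect_equal(m$plan$centers_hz, sqrt(m$plan$edges_hz[-6] * m$plan$edges_hz[-1]))

  flat <- audiogram(rep(30, 9))
  expect_equal(map_bands(flat)$thresholds_db_spl, rep(30, 5))

  # span conservation for an arbitrary valid edge grid
  edges9 <- c(125, 300, 500, 800, 1000, 1600, 2000, 2500, 4000, 6000)
  m2 <- map_bands(audiogram(rep(10, 9), edges9))
  expect_equal(range(m2$plan$edges_hz), range(edges9))

  expect_error(audiogram(rep(30, 8)), class = "wdrcnr_config_error")
  expect_error(audiogram(c(rep(30, 8), -5)), class = "wdrcnr_config_error")
})

test_that("flag pairs map bijectively onto filter indices 1..6", {
  combos <- expand.grid(wdrc = c("soft", "moderate", "loud"),
                        nr = c("off", "on"), stringsAsFactors = FALSE)
  idx <- mapply(function(w, n) filter_index_for(flag_state(w, n)),
                combos$wdrc, combos$nr)
  expect_setequal(idx, 1:6)
  expect_equal(filter_index_for(flag_state("soft", "off")), 1L)
  expect_equal(filter_index_for(flag_state("moderate", "on")), 4L)
  expect_equal(filter_index_for(flag_state("loud", "on")), 6L)
  for (i in 1:6) expect_equal(filter_index_for(flags_for_index(i)), i)
})

test_that("speech-level classification honors the 55/75 dB boundaries", {
  cfg <- engine_config()
  expect_equal(classify_speech_level(54.9, cfg), "soft")
  expect_equal(classify_speech_level(80, cfg), "loud")
  expect_equal(classify_speech_level(55, cfg), "moderate")   # boundary -> moderate
  expect_equal(classify_speech_level(75, cfg), "moderate")
  # monotone ordering along an SPL sweep
  sweep <- classify_speech_level(seq(30, 95, by = 0.5), cfg)
  ord <- match(sweep, c("soft", "moderate", "loud"))
  expect_false(is.unsorted(ord))
  expect_error(classify_speech_level(NaN, cfg), class = "wdrcnr_invalid_input")
})

test_that("engine configuration validates its invariants", {
  expect_error(engine_config(soft_upper_db = 80, loud_lower_db = 75),
               class = "wdrcnr_config_error")
  expect_error(engine_config(decision_rate_frames = 0),
               class = "wdrcnr_config_error")
  expect_error(engine_config(overlap_fraction = 1),
               class = "wdrcnr_config_error")
  cfg <- engine_config()
  expect_equal(cfg$sample_rate_hz, 48000L)
  expect_equal(cfg$frame_len, 256L)
  expect_equal(cfg$decision_rate_frames, 200L)
})

test_that("compression parameters enforce ratio and dynamics constraints", {
  expect_error(compression_params(matrix(0.5, 3, 5), matrix(0, 3, 5)),
               class = "wdrcnr_config_error")
  expect_error(compression_params(matrix(1, 3, 4), matrix(0, 3, 4)),
               class = "wdrcnr_config_error")
  p <- default_compression_params()
  expect_true(all(p$ratios >= 1))
  expect_lt(p$attack_s, p$release_s)
  expect_gte(p$knee_db, 0)
})

test_that("configuration document round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- engine_config(decision_rate_frames = 120L, vad_threshold = 0.6,
                       calibration_offset_db = 97)
  ag <- audiogram(c(15, 20, 25, 30, 35, 40, 45, 40, 35))
  params <- compression_params(matrix(2, 3, 5), matrix(5, 3, 5),
                               attack_s = 0.02, release_s = 0.8)
  write_config(path, cfg, params, ag)
  back <- read_config(path)
  expect_equal(back$cfg, cfg)
  expect_equal(back$params, params)
  expect_equal(back$audiogram, ag)

  # empty document falls back to defaults
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  dflt <- read_config(empty)
  expect_equal(dflt$cfg, engine_config())
  expect_equal(dflt$params, default_compression_params())
})
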
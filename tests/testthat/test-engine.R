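test_that("normalization targets a 0.95 peak and is idempotent", {
  x <- c(0.5, -0.25, 0.1)
  nz <- normalize_audio(x)
  expect_equal(max(abs(nz$audio)), 0.95)
  expect_equal(nz$scale, 1.9)
  again <- normalize_audio(nz$audio)
  expect_equal(again$scale, 1)
  expect_equal(again$audio, nz$audio)
  expect_warning(z <- normalize_audio(numeric(10)))
  expect_equal(z$scale, 1)
})

test_that("closed-form latency matches hand-computed values and the 20 ms budget", {
  expect_equal(algorithmic_latency_ms(engine_config()), 12)   # 10.67 + 1.33
  expect_equal(algorithmic_latency_ms(engine_config(frame_len = 128L), 0),
               2 * 128 / 48000 * 1000)
  expect_lte(algorithmic_latency_ms(engine_config()), 20)
})

test_that("an identity filter reconstructs the input through overlap-add", {
  fs <- fs_default
  set.seed(1)
  x <- 0.3 * sin(2 * pi * 440 * (0:(fs - 1)) / fs) + 0.05 * rnorm(fs)
  unity <- compression_params(matrix(1, 3, 5), matrix(0, 3, 5))
  r <- process(x, engine_config(normalize = FALSE), unity,
               force_filter_index = 1)
  edge <- 512
  keep <- edge:(fs - edge)
  expect_lt(sqrt(mean((r$audio[keep] - x[keep])^2)), 1e-6)
  expect_length(r$audio, length(x))
})

test_that("framing arithmetic yields ceil((n - frame)/hop) + 1 log rows", {
  cfg <- engine_config(normalize = FALSE)
  for (n in c(48000L, 48001L, 40000L, 12800L)) {
    set.seed(2)
    r <- process(rnorm(n, sd = 0.01), cfg)
    expect_equal(nrow(r$logs), as.integer(ceiling((n - 256) / 128) + 1))
    expect_equal(nrow(r$logs), n_frames(n, cfg))
  }
  expect_error(process(rnorm(100), cfg), class = "wdrcnr_invalid_input")
})

test_that("a moderate-speech noisy scene settles on Filter 4", {
  scene <- gen_scene(scene_spec("white", noise_spl_db = 60, speech_spl_db = 65,
                                lead_in_s = 3, speech_s = 5, seed = 7))
  cfg <- scene_engine_config(scene)
  r <- suppressWarnings(process(scene$audio, cfg))
  v <- speech_region_votes(r, scene, cfg)
  expect_gt(nrow(v), 3)
  expect_equal(majority_vote(v$filter_index), 4L)
})

test_that("processing is deterministic and switches only at window boundaries", {
  scene <- gen_scene(scene_spec("pink", noise_spl_db = 45, speech_spl_db = 66,
                                lead_in_s = 1.5, speech_s = 2.5, seed = 31))
  cfg <- scene_engine_config(scene)
  r1 <- suppressWarnings(process(scene$audio, cfg))
  r2 <- suppressWarnings(process(scene$audio, cfg))
  expect_identical(r1$audio, r2$audio)
  expect_identical(r1$logs, r2$logs)

  idx <- r1$logs$filter_index
  changes <- which(diff(idx) != 0)
  # a change logged between frame i and i+1 means the vote fired at frame i
  expect_true(all(changes %% cfg$decision_rate_frames == 0))
  # the cold-start filter is the neutral moderate/NR-off setting
  expect_true(all(idx[1:cfg$decision_rate_frames] == 3L))
  # no sample ever exceeds full scale
  expect_lte(max(abs(r1$audio)), 1)
})

test_that("result objects tidy, glance and plot", {
  scene <- gen_scene(scene_spec("white", noise_spl_db = 45, speech_spl_db = 60,
                                lead_in_s = 1, speech_s = 1.5, seed = 5))
  r <- suppressWarnings(process(scene$audio, scene_engine_config(scene)))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("frame_index", "time_s", "speech_level", "nr_enabled",
                     "vad_prob", "spl_db", "filter_index"))
  gl <- glance(r)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_frames, nrow(r$logs))
  expect_equal(gl$latency_ms, 12)
  expect_s3_class(autoplot(r), "ggplot")
  expect_s3_class(autoplot(r$bank), "ggplot")
  lg <- withr::local_tempfile(fileext = ".log")
  write_frame_log(r, lg)
  lines <- readLines(lg)
  expect_equal(length(lines), nrow(r$logs) + 1L)
  expect_match(lines[2], "^1\\t[0-9.]+\\t-?[0-9.]+\\t3$")
})
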
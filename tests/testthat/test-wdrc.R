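test_that("static gain reproduces hand-computed soft-knee values", {
  # below the knee: linear region, gain is pure makeup
  expect_equal(static_gain_db(-70, gain_curve(2, 8)), 8)
  # above the knee: out = T + (L - T)/R = -42.5; gain = out - L + makeup
  expect_equal(static_gain_db(-40, gain_curve(2, 8)), 5.5)
  # at the threshold: quadratic knee term (1/R - 1)(W/2)^2 / (2W)
  expect_equal(static_gain_db(-45, gain_curve(2, 0)), -0.3125)
})

test_that("static curve is continuous, monotone, and has slope 1/R above knee", {
  for (R in c(1, 1.6, 2.8, 5, 20)) {
    crv <- gain_curve(R, makeup_db = 3)
    out <- function(L) L + static_gain_db(L, crv) - crv$makeup_db
    # continuity at both knee edges (second difference cancels the slope)
    for (edge in c(-45 - 2.5, -45 + 2.5)) {
      h <- 1e-7
      expect_lt(abs(out(edge + h) + out(edge - h) - 2 * out(edge)), 1e-9)
    }
    # monotone output level over a dense sweep
    L <- seq(-90, 0, by = 0.05)
    expect_true(all(diff(out(L)) >= -1e-12))
    # slope above the knee
    slope <- (out(-30 + 1e-4) - out(-30 - 1e-4)) / 2e-4
    expect_equal(slope, 1 / R, tolerance = 1e-6)
  }
})

test_that("unity ratio yields makeup-only gain everywhere, hard knee included", {
  L <- seq(-100, 10, by = 1)
  expect_equal(static_gain_db(L, gain_curve(1, 7)), rep(7, length(L)))
  hard <- gain_curve(4, 0, knee_db = 0)
  expect_equal(static_gain_db(-60, hard), 0)
  expect_equal(static_gain_db(-25, hard), (-45 + 20 / 4) - (-25))
})

test_that("level smoother hits 63% at the attack and release time constants", {
  hop_s <- 128 / fs_default
  crossing_time <- function(levels, start, target, hop_s) {
    frac <- (levels - start) / (target - start)
    k <- which(frac >= 1 - exp(-1))[1]
    (k - 1 + (1 - exp(-1) - frac[k - 1]) / (frac[k] - frac[k - 1])) * hop_s
  }
  n <- 1000
  up <- smooth_level(rep(20, n), smoother(0.01, 1, level_db = 0), hop_s)
  t_att <- crossing_time(up$smoothed_db, 0, 20, hop_s)
  expect_equal(t_att, 0.01, tolerance = 0.05)

  n <- 3000
  down <- smooth_level(rep(0, n), smoother(0.01, 1, level_db = 20), hop_s)
  t_rel <- crossing_time(down$smoothed_db, 20, 0, hop_s)
  expect_equal(t_rel, 1, tolerance = 0.05)
  expect_equal(t_rel / t_att, 100, tolerance = 0.1)

  # constant input is a fixed point
  cst <- smooth_level(rep(-30, 500), smoother(0.01, 1, level_db = -30), hop_s)
  expect_equal(cst$smoothed_db, rep(-30, 500))
})

test_that("band gains equal the makeup row for soft speech below the knee", {
  params <- default_compression_params()
  expect_equal(band_gains_db("soft", params), c(10, 11, 14, 25, 21))
  # forcing unity ratios reproduces any category's makeup row below the knee
  p1 <- compression_params(matrix(1, 3, 5), params$makeup_gains_db)
  for (cat in c("soft", "moderate", "loud")) {
    expect_equal(band_gains_db(cat, p1, representative_level_dbfs = -60),
                 unname(params$makeup_gains_db[cat, ]))
  }
})

test_that("band gains follow the piecewise formula at the loud operating point", {
  params <- default_compression_params()
  # independent evaluation of the piecewise law at L = -20 dBFS
  oracle <- vapply(1:5, function(b) {
    R <- params$ratios["loud", b]
    out <- -45 + (-20 - (-45)) / R
    out - (-20) + params$makeup_gains_db["loud", b]
  }, numeric(1))
  expect_equal(band_gains_db("loud", params, representative_level_dbfs = -20),
               oracle)
})

test_that("category gains are ordered soft >= moderate >= loud in every band", {
  params <- default_compression_params()
  for (lev in c(-50, -35, -20)) {
    g <- vapply(c("soft", "moderate", "loud"), band_gains_db,
                numeric(5), params = params, representative_level_dbfs = lev)
    expect_true(all(g[, "soft"] >= g[, "moderate"]))
    expect_true(all(g[, "moderate"] >= g[, "loud"]))
  }
})
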
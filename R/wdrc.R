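#' Static soft-knee gain curve
#'
#' The feed-forward compressor's input/output law in dB. Below the knee the
#' curve is linear (slope 1); above it the slope is `1/ratio`; across the knee
#' width `W` centered on the threshold `T` a quadratic interpolates smoothly
#' between the two regimes. A knee width of zero gives the hard-knee limit.
#'
#' @param ratio Compression ratio (>= 1).
#' @param makeup_db Makeup gain in dB, added to the returned gain.
#' @param threshold_dbfs Compression threshold in dBFS.
#' @param knee_db Knee width in dB (>= 0).
#' @return An object of class `wdrc_gain_curve`.
#' @export
gain_curve <- function(ratio, makeup_db = 0, threshold_dbfs = -45, knee_db = 5) {
  if (ratio < 1) abort("`ratio` must be >= 1.", class = "wdrcnr_invalid_input")
  if (knee_db < 0) abort("`knee_db` must be >= 0.", class = "wdrcnr_invalid_input")
  structure(list(ratio = ratio, makeup_db = makeup_db,
                 threshold_dbfs = threshold_dbfs, knee_db = knee_db),
            class = "wdrc_gain_curve")
}

#' Static compressor gain at an input level
#'
#' With input level `L`, threshold `T`, knee width `W` and ratio `R`, the
#' output level is `L` below `T - W/2`, `T + (L - T)/R` above `T + W/2`, and
#' `L + (1/R - 1) * (L - T + W/2)^2 / (2 W)` inside the knee. The returned
#' gain is `output - L + makeup`.
#'
#' @param input_level_db Numeric vector of input levels in dBFS.
#' @param curve A [gain_curve()].
#' @return Gain(s) in dB.
#' @export
static_gain_db <- function(input_level_db, curve) {
  stopifnot(inherits(curve, "wdrc_gain_curve"))
  if (any(!is.finite(input_level_db))) {
    abort("Input levels must be finite.", class = "wdrcnr_invalid_input")
  }
  L <- input_level_db
  Tt <- curve$threshold_dbfs; W <- curve$knee_db; R <- curve$ratio
  out <- L
  if (W > 0) {
    in_knee <- abs(L - Tt) <= W / 2
    out[in_knee] <- L[in_knee] +
      (1 / R - 1) * (L[in_knee] - Tt + W / 2)^2 / (2 * W)
  }
  above <- L - Tt > W / 2
  out[above] <- Tt + (L[above] - Tt) / R
  out - L + curve$makeup_db
}

#' Attack/release level smoother
#'
#' One-pole exponential smoothing of a detected level (in dB): the smoothing
#' coefficient is `exp(-hop/attack_s)` while the level rises and
#' `exp(-hop/release_s)` while it falls, so the gain reacts quickly to onsets
#' and recovers slowly.
#'
#' @param attack_s,release_s Time constants in seconds.
#' @param level_db Initial level in dB; `NULL` (default) adopts the first
#'   detected level on the first update.
#' @return An object of class `wdrc_smoother`.
#' @export
smoother <- function(attack_s = 0.01, release_s = 1, level_db = NULL) {
  if (attack_s <= 0 || release_s <= 0) {
    abort("Time constants must be positive.", class = "wdrcnr_invalid_input")
  }
  structure(list(attack_s = attack_s, release_s = release_s,
                 level_db = level_db),
            class = "wdrc_smoother")
}

#' Smooth a detected level trace
#'
#' @param detected_level_db Numeric vector of detected levels in dB,
#'   processed sequentially.
#' @param s A [smoother()].
#' @param frame_hop_s Time step between successive detections, in seconds.
#' @return List with `smoothed_db` (same length as the input) and `s`
#'   (updated smoother carrying the final level).
#' @export
smooth_level <- function(detected_level_db, s, frame_hop_s) {
  stopifnot(inherits(s, "wdrc_smoother"))
  if (frame_hop_s <= 0) {
    abort("`frame_hop_s` must be positive.", class = "wdrcnr_invalid_input")
  }
  a_att <- exp(-frame_hop_s / s$attack_s)
  a_rel <- exp(-frame_hop_s / s$release_s)
  out <- numeric(length(detected_level_db))
  lev <- s$level_db
  for (i in seq_along(detected_level_db)) {
    d <- detected_level_db[i]
    if (is.null(lev)) {
      lev <- d
    } else {
      a <- if (d > lev) a_att else a_rel
      lev <- a * lev + (1 - a) * d
    }
    out[i] <- lev
  }
  s$level_db <- lev
  list(smoothed_db = out, s = s)
}

#' Per-band static gains for a speech category
#'
#' Evaluates the static gain curve in each of the five processing bands using
#' that category's ratio and makeup rows, at the representative operating
#' level for the category (soft -50, moderate -35, loud -20 dBFS by default).
#' These are the gains the corresponding filter-bank filter realizes.
#'
#' @param category `"soft"`, `"moderate"` or `"loud"`.
#' @param params A [compression_params()].
#' @param representative_level_dbfs Operating level in dBFS; defaults to the
#'   category's entry in `cfg$representative_levels_dbfs`.
#' @param cfg An [engine_config()] (source of default operating levels).
#' @return Numeric vector of 5 band gains in dB.
#' @export
band_gains_db <- function(category, params = default_compression_params(),
                          representative_level_dbfs = NULL,
                          cfg = engine_config()) {
  category <- match.arg(category, wdrc_categories)
  if (is.null(representative_level_dbfs)) {
    representative_level_dbfs <- cfg$representative_levels_dbfs[[category]]
  }
  vapply(1:5, function(b) {
    static_gain_db(representative_level_dbfs,
                   gain_curve(params$ratios[category, b],
                              params$makeup_gains_db[category, b],
                              params$threshold_dbfs, params$knee_db))
  }, numeric(1))
}
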
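#' Tidy the per-frame log of a processing run
#'
#' @param x A `wdrc_result` from [process()].
#' @param ... Unused.
#' @return A tibble with one row per frame: `frame_index`, `time_s`,
#'   `vad_prob`, `spl_db`, `filter_index`, `speech_level`, `nr_enabled`.
#' @export
tidy.wdrc_result <- function(x, ...) {
  hop_s <- frame_hop(x$cfg) / x$cfg$sample_rate_hz
  dplyr::mutate(x$logs,
                time_s = (.data$frame_index - 1) * hop_s,
                speech_level = wdrc_categories[(.data$filter_index + 1L) %/% 2L],
                nr_enabled = .data$filter_index %% 2L == 0L,
                .after = "frame_index")
}

#' One-row summary of a processing run
#'
#' @param x A `wdrc_result`.
#' @param ... Unused.
#' @return A tibble with frame/vote counts, the modal filter, the speech
#'   fraction, mean SPL, the normalization scale, the limiter count, and the
#'   closed-form latency.
#' @export
glance.wdrc_result <- function(x, ...) {
  tibble(n_frames = nrow(x$logs),
         n_votes = nrow(x$votes),
         modal_filter = majority_vote(x$logs$filter_index),
         speech_fraction = mean(x$logs$vad_prob >= x$cfg$vad_threshold),
         mean_spl_db = mean(x$logs$spl_db),
         scale = x$scale,
         limited_samples = x$limited_samples,
         latency_ms = algorithmic_latency_ms(x$cfg))
}

#' Tidy a filter bank into per-frequency responses
#'
#' @param x A `wdrc_filter_bank` from [design_filter_bank()].
#' @param fs Sampling rate in Hz.
#' @param n_freq Number of log-spaced evaluation frequencies in 50--8000 Hz.
#' @param ... Unused.
#' @return A tibble: `filter_index`, `category`, `nr_enabled`, `freq_hz`,
#'   `gain_db`.
#' @export
tidy.wdrc_filter_bank <- function(x, fs = 48000, n_freq = 200L, ...) {
  freq <- exp(seq(log(50), log(8000), length.out = n_freq))
  purrr::map_dfr(x, function(f) {
    tibble(filter_index = f$index, category = f$category,
           nr_enabled = f$nr_enabled, freq_hz = freq,
           gain_db = filter_response_db(f, freq, fs))
  })
}

#' Plot the per-frame traces of a processing run
#'
#' SPL (with the category boundaries), speech probability, and the active
#' filter index over time.
#'
#' @param object A `wdrc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wdrc_result <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(
    df, c("spl_db", "vad_prob", "filter_index"),
    names_to = "trace", values_to = "value")
  long$trace <- factor(long$trace, c("spl_db", "vad_prob", "filter_index"),
                       c("SPL (dB)", "P(speech)", "Filter"))
  bounds <- tibble(trace = factor("SPL (dB)",
                                  levels = levels(long$trace)),
                   y = c(object$cfg$soft_upper_db, object$cfg$loud_lower_db))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_hline(data = bounds, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$trace), scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot filter-bank magnitude responses
#'
#' @param object A `wdrc_filter_bank`.
#' @param fs Sampling rate in Hz.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wdrc_filter_bank <- function(object, fs = 48000, ...) {
  df <- tidy(object, fs = fs)
  df$label <- sprintf("Filter %d (%s, NR %s)", df$filter_index, df$category,
                      ifelse(df$nr_enabled, "on", "off"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$gain_db,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Gain (dB)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.wdrc_result <- function(x, ...) {
  cat(sprintf("<wdrc_result> %d samples @ %d Hz | %d frames, %d votes\n",
              length(x$audio), x$cfg$sample_rate_hz, nrow(x$logs),
              nrow(x$votes)))
  cat(sprintf("  modal filter %d | scale %.3f | limiter on %d samples\n",
              majority_vote(x$logs$filter_index), x$scale, x$limited_samples))
  invisible(x)
}

#' @export
print.wdrc_filter_bank <- function(x, ...) {
  for (f in x) {
    cat(sprintf("Filter %d: %s speech, NR %s | band gains [%s] dB\n",
                f$index, f$category, ifelse(f$nr_enabled, "on ", "off"),
                paste(sprintf("%.1f", f$band_gains_db), collapse = ", ")))
  }
  invisible(x)
}
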
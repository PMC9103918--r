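#' Read or write the flat YAML configuration document
#'
#' The whole processing setup -- engine configuration, audiogram, and
#' compression prescription -- round-trips through a single flat YAML
#' key/value document (schema version 1). Every key is optional; missing keys
#' fall back to the package defaults, so an empty file (or no file) yields the
#' reference configuration. Matrix-valued prescription entries are stored as
#' one 5-element sequence per speech category
#' (`ratios_soft`, ..., `makeup_gains_db_loud`).
#'
#' @param path File path of the YAML document.
#' @return `read_config()` returns a list with elements `cfg`
#'   ([engine_config()]), `params` ([compression_params()]) and `audiogram`
#'   ([audiogram()]). `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "wdrcnr_io_error")
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  ver <- doc$schema_version %||% 1L
  if (!identical(as.integer(ver), 1L)) {
    abort(sprintf("Unsupported config schema_version: %s", ver),
          class = "wdrcnr_config_error")
  }
  cfg_keys <- setdiff(names(formals(engine_config)), "representative_levels_dbfs")
  cfg_args <- doc[intersect(names(doc), cfg_keys)]
  if (!is.null(doc$representative_levels_dbfs)) {
    lv <- unlist(doc$representative_levels_dbfs)
    if (length(lv) == 3L) {
      names(lv) <- wdrc_categories
      cfg_args$representative_levels_dbfs <- lv
    }
  }
  cfg <- do.call(engine_config, cfg_args)

  ag_args <- list()
  if (!is.null(doc$audiogram_thresholds_db_spl)) {
    ag_args$thresholds_db_spl <- unlist(doc$audiogram_thresholds_db_spl)
  }
  if (!is.null(doc$audiogram_band_edges_hz)) {
    ag_args$band_edges_hz <- unlist(doc$audiogram_band_edges_hz)
  }
  ag <- if (length(ag_args)) do.call(audiogram, ag_args) else default_audiogram()

  dflt <- default_compression_params()
  row_or <- function(key, fallback) {
    v <- doc[[key]]
    if (is.null(v)) fallback else unlist(v)
  }
  params <- compression_params(
    ratios = rbind(row_or("ratios_soft", dflt$ratios[1, ]),
                   row_or("ratios_moderate", dflt$ratios[2, ]),
                   row_or("ratios_loud", dflt$ratios[3, ])),
    makeup_gains_db = rbind(row_or("makeup_gains_db_soft", dflt$makeup_gains_db[1, ]),
                            row_or("makeup_gains_db_moderate", dflt$makeup_gains_db[2, ]),
                            row_or("makeup_gains_db_loud", dflt$makeup_gains_db[3, ])),
    attack_s = doc$attack_s %||% dflt$attack_s,
    release_s = doc$release_s %||% dflt$release_s,
    threshold_dbfs = doc$threshold_dbfs %||% dflt$threshold_dbfs,
    knee_db = doc$knee_db %||% dflt$knee_db
  )
  list(cfg = cfg, params = params, audiogram = ag)
}

#' @rdname read_config
#' @param cfg An [engine_config()].
#' @param params A [compression_params()].
#' @param ag An [audiogram()].
#' @export
write_config <- function(path, cfg = engine_config(),
                         params = default_compression_params(),
                         ag = default_audiogram()) {
  doc <- list(schema_version = 1L)
  scalar <- setdiff(names(cfg), "representative_levels_dbfs")
  doc <- c(doc, cfg[scalar])
  doc$representative_levels_dbfs <- as.numeric(cfg$representative_levels_dbfs)
  doc$audiogram_thresholds_db_spl <- ag$thresholds_db_spl
  doc$audiogram_band_edges_hz <- ag$band_edges_hz
  for (i in 1:3) {
    doc[[paste0("ratios_", wdrc_categories[i])]] <- as.numeric(params$ratios[i, ])
    doc[[paste0("makeup_gains_db_", wdrc_categories[i])]] <-
      as.numeric(params$makeup_gains_db[i, ])
  }
  doc$attack_s <- params$attack_s
  doc$release_s <- params$release_s
  doc$threshold_dbfs <- params$threshold_dbfs
  doc$knee_db <- params$knee_db
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
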
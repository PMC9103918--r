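Package: wdrcnr
Title: Wide Dynamic Range Compression and Noise Reduction for
    Smartphone-Style Hearing Aid Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline implementation of the signal-processing chain used by
    smartphone-based assistive hearing applications. Audio is processed in
    overlapping short frames; a statistical voice activity detector and a
    fast-weighted sound pressure level meter drive the selection, by majority
    vote over a decision buffer, of one of six filters realizing wide dynamic
    range compression at three speech levels with Wiener-filter noise
    reduction switched on or off. Includes a calibrated SPL meter, soft-knee
    compressor statics with attack/release level smoothing, a linear-phase
    FIR filter bank designed from an audiogram-derived prescription, WAV
    input/output, a command-line entry point, and a synthetic scene generator
    that emulates the noise-lead-in capture protocol for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
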
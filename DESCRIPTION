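Package: hrvload
Title: Heart Rate Variability Analysis Under Combined Cognitive and Physical Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for dual-task (cognitive x physical load)
    heart rate variability studies. Generates fully synthetic study data
    (n-back trial sequences and response logs, autonomically modulated RR
    interval series via an integral pulse frequency modulation model, noisy
    single-lead ECG, NASA-TLX responses), processes raw ECG into cleaned
    normal-to-normal interval series (median/moving-average denoising,
    difference-threshold QRS detection, moving-median outlier screening with
    linear interpolation), extracts time-domain and autoregressive
    frequency-domain HRV features, scores weighted NASA-TLX workload and
    n-back performance, and runs the assumption-gated repeated-measures
    comparison and rank-correlation analysis layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    zoo,
    tibble,
    dplyr,
    tidyr,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
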
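Package: ulperf
Title: Sensor-Based Categorization of Upper-Limb Activity Performance in Daily Life
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying upper-limb (UL) activity performance in
    daily life from bilateral wrist-worn accelerometers. Converts raw 30 Hz
    triaxial recordings into 1 Hz activity-count epochs and a band-limited
    raw path, derives twelve established UL performance variables (movement
    times, magnitudes, use and magnitude ratios, jerk asymmetry, spectral
    arc length), categorizes subjects via z-scored principal components and
    k-means with formal model-fit adjudication (elbow, silhouette, gap
    statistic, MANOVA variance explained, AIC), and quantifies convergent
    and divergent validity against self-report outcomes. Includes a
    synthetic-cohort generator emulating six diagnostic groups so the whole
    pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
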
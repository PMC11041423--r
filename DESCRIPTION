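Package: rhbreath
Title: Respiratory Parameters from Relative-Humidity Breathing Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives respiratory rate and lung-volume proxies (tidal volume,
    inspiratory and expiratory reserve volumes, vital capacity, and the
    deep-breathing area) from relative-humidity breathing waveforms recorded
    by a mask-mounted humidity sensor, and quantifies agreement against a
    reference pneumotach flow channel. Provides a ground-truth-annotated
    synthetic breath simulator, timestamped CSV and IEEE-754 hexadecimal
    telemetry codecs, zero-phase smoothing and resampling, prominence-based
    breath-cycle segmentation with second-derivative refinement of deep
    breaths, rectangle- and triangle-method area-under-curve estimators,
    and agreement statistics (Bland-Altman limits of agreement, one-way
    ANOVA, RMSE, correlation, box summaries), orchestrated by a reproducible
    end-to-end study pipeline.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
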
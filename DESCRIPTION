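Package: spawnsync
Title: Spawning Synchrony and Reproductive Phenology Analysis for Broadcast Spawners
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative reproductive-phenology analysis of broadcast
    spawning marine invertebrates. Implements the weighted daily Marquis
    spawning-synchrony index with fractional weighting of light spawns,
    nightly spawn classification (none/light/heavy), lunar-age annotation of
    observation nights, gametogenesis stage-frequency and oocyte-size
    summaries with one-way ANOVA and Tukey HSD, fragment-to-colony
    reproductive-output scaling, monthly environmental climatologies and
    logistic spawning-predictor models (AIC, Nagelkerke pseudo-R-squared,
    likelihood-ratio p-value), and seeded synthetic-data generators that
    emulate a lunar-cued mass broadcaster and an aperiodic low-volume
    "dribbler" so every analysis stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
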
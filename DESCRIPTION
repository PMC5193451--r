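Package: dendrocycle
Title: Diurnal Cycles and Rain Responses from Automated Dendrometer Band Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing and analysis of automated dendrometer band (ADB)
    time series: ingestion of 15-minute band-logger records onto a regular
    grid, three-stage quality screening against manual caliper checks and
    sensor jump/spike artifacts, smoothing-spline decomposition of
    circumference change into trend, daily increment and diurnal residuals,
    Morlet wavelet coherence and phase-angle classification of daily stem
    shrinkage versus swelling against band temperature, and mixed-effects
    models for climatic drivers of daily amplitude and rain responses of the
    daily increment. Includes a fully parameterized synthetic cohort
    generator (weather, tree signals, instrument faults) so that every stage
    is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
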
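Package: phenoLAI
Title: Multi-Season Cropland Phenology from Combined Satellite LAI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for characterizing cropland land surface phenology from
    green leaf area index (LAI) time series derived from two optical satellite
    data streams. Provides Gaussian process regression for multiband LAI
    retrieval and time-series gap-filling, Savitzky-Golay smoothing of
    irregularly sampled series, two-sensor stream fusion, amplitude-threshold
    detection of up to two growing seasons per year (start, end, length and
    area of season), cropping-frequency and phenology mapping, and per-crop
    statistical evaluation. Includes a synthetic-data generator emulating
    single- and double-cropping irrigated systems so the full pipeline is
    testable without external imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    signal,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
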
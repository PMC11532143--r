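Package: fermfuse
Title: Multi-Source Fermentation Data Fusion, Off-Gas Physiology, and
    Batch Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for fusing heterogeneous fermentation monitoring
    streams (online bioreactor sensors, at-line off-gas mass
    spectrometry, offline manual assays) onto a common time grid,
    computing derived physiological parameters (carbon-dioxide evolution
    rate, oxygen uptake rate, respiratory quotient, and process-,
    reactor- and cell-level rates and yield coefficients), rule-based
    device fault identification, multi-batch key-feature analytics
    (Spearman screening and two principal-component procedures), and a
    soft-sensor pipeline for real-time biomass estimation. Includes a
    synthetic fed-batch simulator with fault injection used as the test
    bed, a scaled-integer register codec for spectrometer transport
    payloads, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
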
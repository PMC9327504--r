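Package: wsisim
Title: Throughput Simulation and Quality-Control Modelling for Whole-Slide Scanning Operations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and benchmarking high-throughput whole-slide
    imaging (WSI) operations in digital pathology. Provides the normalized
    scan-time metric (scan duration rescaled to a 15 x 15 mm reference tissue
    area) for cross-scanner comparison, line- and tile-scanner effective-area
    geometry, per-slide scan-time models, a Monte-Carlo engine for an
    AI-enabled quality-control workflow with automatic stringent rescans,
    visual review and control sampling, closed-form miss- and flag-rate
    oracles for a noisy threshold classifier of image quality, parameter
    sweeps over rescan rates and detection thresholds, parallel scanner-fleet
    scheduling, and a bundled benchmark of nine slides scanned on four
    commercial scanners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
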
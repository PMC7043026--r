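Package: slscan
Title: Smart Line Scan Analysis for High-SNR Population Calcium Imaging
Version: 0.1.0
Authors@R: person("slscan", "developers", role = c("aut", "cre"),
    email = "slscan@example.org")
Description: Tools for smart line scan (SLS) two-photon calcium imaging of
    neuronal populations: pixel-wise SNR segmentation of raster reference
    t-series, genetic-algorithm optimization of closed scan trajectories,
    motion-artifact detection and SNR-based pixel reassignment, neuropil
    decontamination, calcium-event detection with spike-accuracy scoring,
    neuronal-ensemble detection with surrogate coactivity thresholds and
    non-negative matrix factorization, and a dwell-time-accurate synthetic
    scene simulator providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
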
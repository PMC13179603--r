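Package: dmscc
Title: Growth, Biosensor and Chip Analysis for Dynamic Microfluidic
    Single-Cell Cultivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for dynamic microfluidic single-cell
    cultivation (dMSCC) experiments in which yeast microcolonies are
    exposed to second-scale square-wave oscillations between glucose
    excess and limitation.  Provides a model of the oscillating on-chip
    environment with per-array time shifts and along-array pulse
    smoothing, dye-trace pulse-fidelity estimation, an agent-based
    generator of synthetic per-cell segmentation tables, log-linear
    growth-rate estimation with sliding-window maximal rates, an
    adaptation-time statistic from the intersection of initial and
    maximal growth fits, ratiometric biosensor (ATP and glycolytic flux)
    and cell-size population statistics with excess-control
    normalization, Monod goodness-of-fit, and condition-sweep reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
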
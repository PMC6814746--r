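Package: nucspike
Title: Nuclear Calcium Spike Detection and Cohort Analysis for Root Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of single nuclear calcium
    transients in fluorescence time series from growing plant root
    meristems. Implements baseline normalisation (dF/F), polynomial
    detrending, gradient-threshold pulse-boundary detection, rise/fall/
    duration measurement, nuclear-versus-cytosolic origin classification
    from dual-channel recordings, and cohort-level summaries (responder
    fractions, spike rates within a reference meristem span, zone
    partitions, growth-rate regression). Includes a seeded synthetic-data
    generator with exact ground truth for benchmarking, and a minimal
    imaging front end (background subtraction, circular-ROI mean-intensity
    extraction, multi-page TIFF input/output).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tools
Config/testthat/edition: 3
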
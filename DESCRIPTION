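Package: gelquant
Title: Densitometric Protein Quantification from SDS-PAGE Gel Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies proteins directly in photographed one-dimensional
    SDS-PAGE gels. Converts gel photographs into per-lane densitograms,
    corrects baselines and integrates band peaks as in chromatography,
    fits a quadratic-through-origin calibration of protein mass against
    peak area from serial-dilution lanes run on the same gel, estimates
    molecular weights against a marker ladder, and computes degradation
    degrees for treated versus untreated samples. Includes a synthetic
    gel-photograph generator with exact ground truth for validation, and
    a scriptable end-to-end pipeline driven by YAML run configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jpeg,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
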
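Package: punctaline
Title: Quantification of Fluorescent Puncta in Linear Cellular Structures
Version: 0.1.0
Authors@R: person("punctaline", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Batch analysis of punctate fluorescent protein accumulation along
    linear cellular structures such as the ventral and dorsal nerve cords of
    C. elegans. Reads grayscale TIFF stacks, computes maximum-intensity
    projections, straightens a traced polyline path into a linescan image,
    detects puncta by Gaussian smoothing followed by Phansalkar local adaptive
    thresholding and minimum-size filtering, measures per-punctum intensity
    and Gaussian-fit full width at half maximum (FWHM) with a misfit discard
    rule, and reports per-image puncta density. Includes a seeded synthetic
    linescan generator with ground truth for validation, shipped detection
    presets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
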
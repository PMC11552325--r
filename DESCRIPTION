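Package: stroi
Title: Image-Guided Region-of-Interest Analysis for Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns tissue-image segmentation masks with spatial
    transcriptomics spots, filters masks by spot co-location, builds
    user-defined or automatically proposed regions of interest (ROIs),
    and runs downstream statistics between ROIs: Wilcoxon rank-sum
    differential expression with Benjamini-Hochberg correction,
    hypergeometric over-representation analysis against GMT gene-set
    libraries, and cell-type proportion comparison from externally
    computed deconvolution fractions. Segmentation is a pluggable
    backend contract, with a deterministic colour-clustering reference
    segmenter built in, so promptable deep-learning segmenters such as
    SAM can be dropped in but are never required. Includes a synthetic
    Visium-style fixture generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    tools,
    methods
Suggests:
    tiff,
    jpeg,
    rhdf5,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
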
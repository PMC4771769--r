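Package: aispuncta
Title: Quantification of Fluorescent Puncta Enrichment on the Axon Initial Segment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying punctate immunofluorescence
    (e.g., GABA-A receptor alpha-subunit clusters) in paired axon initial
    segment (AIS) and non-AIS regions of interest from single-optical-section
    confocal images. Implements rolling-ball background subtraction, triangle
    auto-thresholding, connected-component particle analysis with area and
    circularity gates, per-ROI cluster morphometry, the AIS enrichment-ratio
    statistic, ROI-restricted Pearson and Manders colocalization with Costes
    auto-thresholding, and the associated inferential stack (two-way and
    one-way ANOVA, Bonferroni planned comparisons, Tukey-Kramer HSD). Includes
    a synthetic fluorescence scene simulator with planted ground truth so that
    every stage can be validated without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
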
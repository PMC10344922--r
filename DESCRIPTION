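Package: slideroi
Title: Region-of-Interest Detection and HER2 Concordance Analysis for Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("slideroi", "developers", email = "slideroi@example.org", role = c("aut", "cre"))
Description: Tools for automated region-of-interest (ROI) detection on
    pyramidal whole-slide images in digital pathology: multi-resolution
    pyramid handling and 224x224 tile extraction, intensity-based tile
    screening with pluggable artifact and quality gates, multi-pathologist
    consensus labeling with balanced dataset splitting and stratified
    cross-validation, enumeration of classification-head architectures and
    hyperparameter grids for transfer-learning model selection, a
    desk-scale frozen-backbone tile classifier, end-to-end slide level ROI
    mapping with coordinate transfer to serial sections, HER2/CEP17
    signal-count grading, and inter-observer agreement statistics (MSE,
    Pearson correlation, Cohen's kappa). Includes a fully synthetic
    slide/annotation/signal-count generator so the entire pipeline is
    testable without any real slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    digest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
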
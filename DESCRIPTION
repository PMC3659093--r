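Package: tmakit
Title: Metadata-Aware Tissue Microarray Core Tracking, Scoring and Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for managing tissue microarray (TMA) studies: a Common Data
    Element (CDE) metadata registry with value-domain validation, recipient-block
    layout (slidemap) handling with CSV import and XML round-tripping, synthetic
    stained-core image generation, scanner-style image export and Deep Zoom (DZI)
    pyramid tiling, standardized immunohistochemistry scoring systems including
    the Allred composite score with ER status classification, score heatmap and
    virtual-slide rendering, a hierarchical study/marker/scorer document store
    with advisory permissions, tabular export, and TMA Data Exchange
    Specification (TMA DES) XML import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    png,
    jpeg,
    digest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
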
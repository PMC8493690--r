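Package: sarcscreen
Title: High-Content Quantification of Sarcomere Integrity and YAP1
    Nuclear Localization in iPSC-Cardiomyocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An image-analysis and statistics pipeline for high-content
    screening of drug-induced sarcomere disruption in human iPSC-derived
    cardiomyocytes. Segments nuclei and per-cell territories from
    two-channel fluorescence fields, measures alpha-actinin Z-line segment
    lengths by ridge enhancement and skeletonization, classifies cells as
    having well-organized sarcomeres (mean Z-line length above a cutoff),
    and aggregates the Healthy Sarcomere Index (HSI) per well. A parallel
    low-magnification branch scores YAP1 nuclear-to-cytoplasmic enrichment
    per cell and the per-well nuclear-localization index. Dose-response
    inference uses Williams' and Shirley-Williams' step-down trend tests
    with a variance-heterogeneity gate, plus two-group t / Wilcoxon
    comparisons. A synthetic-plate simulator with per-cell ground truth
    makes every stage testable without microscope data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    EBImage,
    tiff,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
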
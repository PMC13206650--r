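Package: circasync
Title: Cross-Tissue Temporal Coordination Analysis of Circadian Expression Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies the temporal coordination of gene expression across
    tissues in multi-tissue circadian time-course experiments. Provides
    intra-tissue and inter-tissue Pearson-correlation synchronization metrics
    (mean absolute correlation, significant-pair counts, 1 - r complete-linkage
    clustering), a per-gene signed whole-body synchronization score with a
    benchmark-calibrated "clock-like" threshold, temporal wave clustering of
    globally synchronized genes, hierarchical pathway-term frequency and ratio
    enrichment, and peak-to-trough amplitude statistics. Includes a
    ground-truth synthetic-data generator emulating a 22-tissue, 2-hourly,
    two-condition feeding-schedule design, and an end-to-end reproducible
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
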
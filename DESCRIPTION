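Package: spotzoner
Title: Compartmental Zonation of Spatial Transcriptomics Spots by
    Tissue-Boundary Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies Visium and Visium HD spatial transcriptomics spots
    into ordinal compartmental zones according to their relative distance
    from a tumor/parenchyma boundary. Binary tissue-occupancy lattices are
    smoothed with missing-aware square moving averages at two window sizes,
    combined into weighted composite boundary-distance scores, and
    thresholded into eight (or more) zones spanning inner tumor to distant
    parenchyma. Includes quality control and log-normalization for 10x-style
    count matrices, zone-wise profiling statistics (one-vs-rest Wilcoxon
    differential expression, gene-signature module scores, per-zone median
    summaries), a synthetic Visium-like data generator for end-to-end
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
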
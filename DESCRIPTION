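Package: tissueconcord
Title: Cross-Platform Concordance of Tissue-Specific Gene Expression Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives binary gene presence/absence calls per tissue under
    three detection-platform rules (microarray P/M/A calls aggregated over
    replicates and probesets, exon-array detection-above-background p-values
    thresholded at the replicate median, and RNA-seq RPKM thresholding with
    multi-sample averaging), quantifies cross-platform concordance with the
    Matthews correlation coefficient, classifies genes by tissue breadth
    (absent, tissue-specific, intermediate, universal), and propagates calls
    to protein interactions (present iff both partners expressed) and
    protein complexes (complete/partial/absent with detection percentages).
    Includes a synthetic-data generator with planted platform sensitivities
    and false-positive rates so every stage is testable without external
    expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
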
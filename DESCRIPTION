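Package: motifmc
Title: Monte Carlo Promoter Motif Enrichment and Worm Behavioral Assay
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing enrichment of transcription-factor binding
    motifs (such as the XBP-1s-associated UPRE elements) in promoter windows
    of differentially expressed gene sets, using a Monte Carlo resampling
    null over random gene sets drawn from a length-filtered background.
    Includes strand-aware promoter extraction from FASTA/GFF3, IUPAC
    consensus and position-weight-matrix scanning with exact
    score-distribution thresholding, reference gene-set overlap accounting,
    quantification of C. elegans food-leaving and exploration-grid assays,
    and a synthetic-genome and behavior simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
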
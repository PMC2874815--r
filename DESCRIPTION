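Package: estsurvey
Title: Analytics for Normalized EST Sequencing Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Statistics and sequence-mining tools for expressed sequence tag
    (EST) surveys built from normalized cDNA libraries: Lucy-style quality
    trimming of Sanger reads, per-library redundancy statistics (empirical and
    Good-Turing coverage, reads-per-discovery), EST completeness
    classification against protein entries, microsatellite (SSR) mining with
    Sputnik-style parameters, candidate-SNP filtering with
    transition/transversion classification, and a synthetic EST-survey
    simulator with a second-order reassociation-kinetics model of
    duplex-specific-nuclease (DSN) normalization so every stage is testable
    against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
RoxygenNote: 7.3.3
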
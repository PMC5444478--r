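Package: seminalseq
Title: Transcriptome Analysis of Maize Embryo Seminal Root Initiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end RNA-Seq analysis pipeline for comparing wild-type
    and rtcs mutant maize embryo transcriptomes across developmental stages:
    Bayesian gene-activity calling under a negative-binomial mixed model with
    empirical-Bayes shrinkage, TMM/FPKM normalization with length/GC offsets,
    moderated differential expression with lane blocking, dynamic
    expression-pattern classification, LBD promoter-motif scanning, and
    functional-category and synteny enrichment with Yates-corrected chi-square
    tests. Includes a synthetic-data generator with known ground truth so
    every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    limma,
    edgeR,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
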
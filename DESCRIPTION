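Package: ntrkscan
Title: NTRK Fusion Detection, Classification and Cohort Statistics for
    Targeted Panel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale reimplementation of a clinical DNA fusion-detection
    workflow for NTRK1/2/3 rearrangements in solid tumors. Includes a
    discordant read-pair structural-variant caller (discordant-pair
    collection, proximity clustering, greedy contig assembly and split
    realignment confirmation with a unique-support filter), a gene-model
    based fusion annotator implementing the definite/likely functional
    classification (in-strand, in-frame, kinase-domain retention, known
    partner and hot-exon rules), panel-level tumor mutational burden and
    microsatellite instability metrics, cohort prevalence and enrichment
    statistics, and a synthetic-data generator that plants rearrangements,
    microsatellite profiles and cohorts with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
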
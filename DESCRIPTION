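Package: tigrkit
Title: Detection, Processing and Target Prediction for Tandem Interspaced
    Guide RNA (TIGR) Arrays
Version: 0.1.0
Authors@R:
    person("tigrkit", "developers", email = "tigrkit@example.org",
           role = c("aut", "cre"))
Description: Toolkit for TIGR-Tas RNA-guided systems. Detects and annotates
    TIGR guide-RNA arrays (dual-repeat and stem-loop forms) in nucleotide
    sequence, derives mature 36-nt-class tigRNAs from array models, predicts
    tandem-spacer DNA target sites with cleavage geometry (C-5 cut rule,
    3-prime overhangs, seed and nickase mismatch rules, gap tolerance), and
    designs tigRNAs plus minimal expression arrays for user-chosen targets.
    Includes a seed-deterministic synthetic-data generator producing
    ground-truthed loci, target genomes and read evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
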
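Package: mgeclass
Title: Phage, Chromosome and Plasmid Classification of Metagenomic
    Fragments with a Dual-Path Convolutional Network
Version: 0.1.0
Authors@R:
    person("mgeclass", "developers", email = "mgeclass@example.org",
           role = c("aut", "cre"))
Description: Identifies mobile genetic elements (phages and plasmids) among
    assembled metagenomic DNA fragments. Each fragment is encoded twice, as a
    per-base one-hot matrix over the forward and reverse-complement strands
    and as a per-codon one-hot matrix over all six reading frames, and the two
    encodings feed separate convolutional paths of a dual-path network whose
    softmax head scores the fragment as phage, chromosome or plasmid. Long
    sequences are scanned with non-overlapping 1,200 bp windows routed to
    length-matched models and aggregated by length-weighted averaging. The
    package also ships a seeded fragment simulator (Markov-chain reference
    "genomes", uniform fragment lengths, substitution and indel error
    channels), three-class evaluation machinery (confusion matrices,
    one-vs-rest TPR/FPR/AUC, threshold sweeps, lifestyle/transmissibility
    score transforms) and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
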
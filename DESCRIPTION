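Package: mirloop
Title: Modeling and Detection of Intronic miRNA-Mediated Self-Loops
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and stochastic models of gene autoregulation via
    intronic microRNAs: a host gene co-transcribed with an intronic miRNA
    that represses its translation (iMSL), compared under mathematically
    controlled conditions with a simple transcription unit and a
    transcriptional self-loop.  Includes ODE-based response-time and
    ON-state robustness analyses, adaptation and Weber's-law metrics with
    parameter-space classification, exact Gillespie simulation with a linear
    noise approximation for noise-buffering maps, and a permutation test for
    the over-representation of intronic-miRNA self-loops in synthetic
    annotation plus target-prediction networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    yaml,
    rtracklayer,
    S4Vectors,
    BiocGenerics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
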
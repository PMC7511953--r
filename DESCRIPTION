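Package: ribocomp
Title: Ribosome Competition Modelling of Translation Under Elongation-Factor Depletion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mechanistic modelling of transcript competition for a limited pool of
    free ribosomes, built around a closed-form steady-state protein-yield model,
    a whole-transcriptome ribosome-conservation solver with polysome-profile
    prediction, and a stochastic lattice (exclusion-process) simulator of
    elongation with a two-phase per-codon dwell (elongation-factor recruitment
    followed by charge-dependent translocation). Includes a synthetic-omics
    generator producing paired mRNA-seq/Ribo-seq count matrices for control
    versus elongation-factor-knockdown conditions with a high-initiation-rate
    (TOP-like) gene class, and a self-contained translation-efficiency analysis
    stage (median-of-ratios normalisation, permutation tests, Benjamini-Hochberg
    correction, rank-based class enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
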
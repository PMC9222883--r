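Package: omegascan
Title: Parallel Detection of Positive and Negative Selection on Protein-Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood codon substitution models for measuring
    selection pressure (dN/dS) on in-frame coding alignments. Implements the
    classic site models (M0, M1a, M2a, M7, M8), branch models and branch-site
    models with exhaustive enumeration of single foreground branches,
    automated likelihood-ratio tests with chi-squared p-values, naive and
    Bayes empirical Bayes identification of selected sites, and a per-site
    fixed-effects likelihood (FEL) scan that detects both positive and
    negative selection. A task-based orchestrator runs all tests in parallel
    with safe restart/resume, and results are compiled into a per-codon
    overview table, a highlighted FASTA file and p-value-annotated trees.
    Includes a phylogenetic codon-sequence simulator for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    parallel,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
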
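Package: moanet
Title: Drug Mechanism-of-Action Inference on Signed Protein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the molecular mechanism of action of a drug in a disease
    phenotype on a signed directed protein-interaction network. Drug targets
    are clamped to their modulation sign and a damped saturating signal
    propagation predicts downstream protein activity; weight assignments are
    fitted by simulated annealing against expression-derived sign
    restrictions, yielding an ensemble of plausible solution models. The
    ensemble is summarised by an effector sign-reversal intensity statistic
    per pathophysiological motif, single-target contributions, multi-drug
    benchmarking, a degree-preserving network proximity score, and a
    most-supported mechanism-of-action subnetwork. Companion tools derive
    restrictions from two-cohort expression matrices (Lilliefors-gated
    t/Wilcoxon tests with Benjamini-Hochberg correction), summarise paired
    clinical bioflag panels as percent delta changes, and generate complete
    synthetic study scenarios with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    nortest,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
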
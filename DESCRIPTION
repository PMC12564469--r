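Package: g4causal
Title: Causal Bayesian Networks for G-Quadruplex Thermostability and
    Chromatin Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps in vitro G-quadruplex (G4) thermostability (G4-Seq mismatch
    percentage), evolutionary conservation (phyloP), chromatin state,
    chromatin accessibility (ATAC-Seq) and transcription-factor occupancy
    onto endogenous G4 (eG4) regions, and infers causal Bayesian networks
    among these signals.  Structure learning uses the order-independent
    PC-stable algorithm with a Monte-Carlo permutation test of Pearson's
    chi-squared for conditional independence, wrapped in a stratified-sampling
    bootstrap with N-of-10 average models, a common network across trials,
    and accuracy/coverage/AUC robustness summaries.  A synthetic-data module
    simulates discrete observations from a known ground-truth DAG and builds
    toy genome fixtures so every stage of the pipeline can be verified
    against a recoverable truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
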
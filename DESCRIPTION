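Package: helipause
Title: Sequence-Dependent Helicase Unwinding Kinetics and Pause Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling and analysing sequence-dependent DNA unwinding
    by helicases on hairpin and forked substrates. Provides nearest-neighbor
    duplex energetics with monovalent-salt correction, stochastic unwinding
    simulators for simultaneous-melting and delayed-release kinetic stepping
    models, a worm-like-chain measurement model producing noisy single-molecule
    extension traces, two step-finding algorithms (recursive Welch t-test
    segmentation and iterative chi-square step placement), dwell-time and pause
    statistics, reduced chi-square kinetic step-size model selection, n-step
    single-turnover ensemble kinetics with productive-fraction branching, and a
    binomial nucleotide-analog competition model of mechano-chemical coupling.
    All inputs are generated synthetically with controlled ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    yaml
Config/testthat/edition: 3
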
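Package: bfpmech
Title: Analysis of Biomembrane Force Probe Single-Bond Mechanics and
    Mechanotransduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing biomembrane force probe (BFP)
    single-bond experiments on mechanoreceptors such as platelet GPIb-alpha.
    Provides a synthetic-data generator for force-ramp and force-clamp test
    cycles with ground-truth labels; detection of bond outcomes, lifetimes and
    force-induced domain-unfolding events in force-time traces; worm-like-chain
    (WLC) contour-length fitting; kernel-density classification of unfolding
    lengths; exponential, dual-exponential and Bell-model dwell-time kinetics
    with a joint-probability model of cooperative domain unfolding;
    chi-square cooperativity statistics; and linkage of bond mechanics to
    classified single-cell calcium responses, including ROC threshold
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
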
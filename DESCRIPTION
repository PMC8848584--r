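Package: spikesae
Title: Classification of Nerve Discharge Rhythms with Stacked Sparse
    Auto-Encoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the four basic nerve discharge rhythms (periodic,
    random-alternating, chaotic, integer-multiple) with the Chay
    ion-channel neuron model and its stochastic and improved-deterministic
    variants, extracts interspike-interval (ISI) sequences from the
    simulated membrane traces, and classifies fixed-length normalized ISI
    sequences with a stacked sparse auto-encoder whose learned code is
    fused with two hand-crafted time-series features (a dispersion
    statistic and approximate entropy) before a Softmax classifier.
    Includes an archetype-based synthetic dataset builder, KNN and SVM
    comparison baselines, confusion-matrix evaluation, and a feature
    ablation runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
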
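Package: protospike
Title: Spike-Train Analysis and Protoneural Network Models for Proteinoid Microspheres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spontaneous electrical activity of
    proteinoid microspheres ("protoneurons") and for modelling them as
    minimal neural networks. Provides synthetic generation of spiking
    potential/current traces with controlled spike statistics, the
    differential pulse voltammetry (DPV) excitation program, threshold-based
    spike detection with a minimum peak distance, interspike-interval and
    firing-frequency statistics, a latency temporal-coding scheme with a
    bounded Hebbian co-activation weight update and first/second-order
    connectivity indices, leaky integrate-and-fire and continuous rate
    network simulators, and an ordinary-least-squares QSAR model relating
    mean firing rate to molecular weight and peptide length. All generators
    are seeded and fully deterministic, so every pipeline stage is testable
    without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
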
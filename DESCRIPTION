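Package: revlearn
Title: Reversal-Learning Analysis for Drosophila Calcium Imaging, Behavior and
    Connectomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for olfactory reversal-learning
    experiments in Drosophila. Converts two-channel (GCaMP/tdTomato)
    ROI fluorescence traces into ratiometric dR/R0 signals with
    double-exponential photobleaching correction, quantifies odor- and
    shock-evoked responses in stimulus-locked windows, and computes
    trial-difference learning statistics with a normality-gated paired test
    battery and Greenhouse-Geisser-corrected repeated-measures ANOVA with
    Dunnett-style post-hoc comparisons. Also computes quadrant-arena
    preference and avoidance indices, and pairwise synapse-count summaries
    from connectome synapse tables. Ships a synthetic-data generator that
    emulates photobleaching, shared multiplicative motion artifacts,
    trial-dependent response plasticity, binomial quadrant occupancy and
    synapse tables with known ground truth, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    mvtnorm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
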
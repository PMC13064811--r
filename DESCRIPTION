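Package: nmdarkinetics
Title: Kinetic Analysis of NMDA-Receptor Gating, Open Probability, and
    Excitotoxicity Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of NMDA-receptor (NMDAR)
    whole-cell electrophysiology and the downstream cell-biology assays that
    accompany it. Implements a four-state gating scheme (desensitized, closed,
    open, blocked) for open-channel blockers such as MK-801, estimation of
    microscopic open probability from MK-801 blocking kinetics,
    single/double-exponential trace decomposition with weighted time
    constants, Hill-equation fits of agonist concentration-response and
    antagonist inhibition curves, a two-component Gaussian-mixture classifier
    for pyknotic nuclei in excitotoxicity assays, fluorescence ratio metrics
    (surface/total, Golgi colocalization) and rule-based dendritic-spine
    classification, plus synthetic-data generators that emulate the
    recording and imaging conditions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    mclust,
    tiff,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
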
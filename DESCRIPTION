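Package: iegcoupling
Title: Coupled Analysis of Calcium Activity and Immediate-Early-Gene Reporter Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for chronic two-photon experiments that record
    neuronal calcium activity (red indicator channel) together with GFP-based
    immediate-early-gene (IEG) reporter expression (Arc, c-Fos, EGR1) in mouse
    visual cortex. Implements ROI fluorescence extraction and median-based
    dF/F, the per-mouse min/median IEG normalization, time-lagged
    population-vector correlation between activity and expression,
    expression-pattern dynamics across visuomotor learning conditions
    (condition-boundary change statistics, linear trends, rank-order pattern
    similarity), and event-triggered functional characterization of high-IEG
    neurons (running onsets, gratings, visuomotor mismatch, open-loop behavior
    correlations). A self-contained synthetic-data generator produces
    behavior, spiking, fluorescence and delayed IEG induction with known
    ground truth so that every stage has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
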
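Package: cotune
Title: Co-Tuned Ensemble Rebalancing Analysis for Two-Photon
    Photostimulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-photon calcium-imaging experiments in
    which small ensembles of frequency-tuned auditory-cortex neurons are
    holographically photostimulated during tone presentation. Provides a
    ground-truthed synthetic multi-session experiment generator, neuropil
    correction and dF/F trial epoching, responsiveness and frequency-
    preference classification with selectivity tertiles, per-cell
    session-difference (stimulation and post-stimulation) effects with
    target-distance geometry and permutation nulls, a mixed-effects ANOVA
    back end with estimated-marginal-means contrasts and Holm-corrected
    tertile post hocs, three-parameter exponential-decay fits with extra
    sum-of-squares F-tests, and a suppression-regime network simulation
    that compares rebalancing hypotheses (suppression of all, random, or
    co-tuned non-target neurons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    emmeans,
    graphics,
    grDevices,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
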
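Package: optoentrain
Title: Analysis of Optogenetic Pulse-Train Entrainment, Spike-Field
    Coherence, and Operant Behavior in Electrophysiological Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing electrophysiological recording sessions
    collected during pulsatile optogenetic stimulation and operant
    behavior. Implements spike-phase locking to pulse trains with the
    Rayleigh test, spike-triggered averages and normalized spike-field
    coherence, firing-rate modulation classification with a
    normality-gated choice between paired t and Wilcoxon signed-rank
    tests, LFP gamma band-power epoch analysis with artifact rejection,
    reinforcement-schedule engines (CRF, fixed-ratio, variable-interval),
    discrimination-learning performance statistics with repeated-measures
    ANOVA, and a synthetic session generator with known ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    nortest,
    signal,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
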
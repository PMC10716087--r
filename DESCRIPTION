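Package: pupilbreadth
Title: Attentional-Breadth Pupillometry: Design, Simulation and Mixed-Effects Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for covert spatial-attention cueing experiments in which
    attentional breadth (near/medium/far eccentricity) is manipulated and pupil
    size is the dependent measure. Provides reproducible session-design
    generation with counterbalanced cue-symbol mappings and exact 80/20 cue
    validity, n-up-1-down opacity staircases, a synthetic-observer and
    1000-Hz pupil-trace generator with a cue-locked light response and a
    ramping eccentricity effect, the standard pupillometry preprocessing chain
    (blink interpolation, downsampling, millimetre conversion, baseline
    correction, z-score outlier flagging), four-fold cross-validated
    time-window selection with confirmatory linear mixed-effects models, and
    the behavioral analyses (mixed logistic cue-validity model, reaction-time
    model, repeated-measures JZS Bayes factor for staircase efficacy, and
    deviance-based iterative participant exclusion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
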
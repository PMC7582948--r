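Package: threatcode
Title: Threat-Probability and Fear-Output Coding Analysis for Single-Unit
    Recordings in Pavlovian Fear Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for single-unit recordings collected during
    Pavlovian fear discrimination over a baseline of rewarded nose poking.
    Computes per-trial conditioned suppression ratios, peri-event spike
    binning with differential and Z-score normalization, screens units into
    cue-excited / cue-inhibited / outside-selection-criteria classes with
    Bonferroni-corrected paired t tests, fits trial-by-trial linear encoding
    models with fear-output and threat-probability regressors, sweeps the
    uncertainty-cue probability assignment to produce threat-tuning curves,
    and provides the population statistics (chi-square proportion tests,
    mixed-design ANOVA with partial eta squared, Pearson firing/signaling
    coupling, Fisher r-to-z comparison of correlations). Includes a seeded
    synthetic session generator (piecewise-homogeneous Poisson nose poking,
    inhomogeneous Poisson spike trains) so every stage is verifiable against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
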
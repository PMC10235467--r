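Package: lnvlight
Title: Light-Evoked Firing and Arousal Analysis for Drosophila l-LNv Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for light-evoked electrophysiology and
    behavioral arousal in the Drosophila circadian/arousal circuit. Detects
    action potentials in current-clamp voltage traces of large ventral lateral
    neurons (l-LNvs), computes light-on versus baseline firing-frequency (FF)
    ratios and post-stimulus decay profiles under a dark/light/dark sweep
    protocol, scores sleep and light-pulse arousal from TriKinetics-style
    activity-monitor files using the 5-min inactivity sleep rule, and applies
    normality-gated two-sample inference (Anderson-Darling gate, F-test choice
    of pooled versus Welch t, Mann-Whitney fallback) with Benjamini-Hochberg
    FDR control. Ships parameterized synthetic-data generators (inhomogeneous
    Poisson spike trains with refractoriness, rendered voltage traces,
    alternating sleep/wake activity records) so every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    nortest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
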
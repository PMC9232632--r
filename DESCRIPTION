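Package: nicheDSS
Title: Multiparametric Ex Vivo Drug Sensitivity Screening for Primary AML
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computational readout for niche-like ex vivo drug sensitivity
    screens of primary acute myeloid leukemia samples profiled by
    multiparameter flow cytometry. Provides a synthetic event-level flow
    data generator with known ground truth, deterministic automated
    hierarchical gating (viability, GFP+ stromal exclusion, lymphocyte
    split, GPR56 x differentiation-marker quadrants), vehicle (DMSO)
    normalization of per-well cell counts, untruncated trapezoidal
    area-over-the-curve (AOC) drug activity scoring, fixed-ratio dilution
    series and PK/toxicity-bounded screening-concentration selection,
    response-pattern classification (cytotoxic, stemness-specific,
    differentiating), lymphocyte-referenced chemosensitivity calls, and
    population-level combination-benefit statistics with
    Benjamini-Hochberg false discovery control.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
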
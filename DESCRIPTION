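Package: ohcpbpk
Title: Minimal PBPK Modelling of 4beta-Hydroxycholesterol as a Hepatic
    CYP3A Biomarker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parent-metabolite physiologically based pharmacokinetic (PBPK)
    modelling of cholesterol and its CYP3A-specific oxysterol metabolite
    4beta-hydroxycholesterol (4beta-OHC), an endogenous biomarker of hepatic
    CYP3A activity. Provides reverse translation of in vivo clearances to
    per-enzyme intrinsic clearances through the well-stirred liver model,
    analytic and ODE steady-state simulation of baseline and inducer-perturbed
    4beta-OHC in virtual populations (including CYP3A4*22 and CYP3A5 genotype
    and rheumatoid-arthritis templates), trial-level drug-drug interaction
    protocols, fraction-metabolized calibration, meta-analysis pooling of
    literature study tables, and fold-error model assessment statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
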
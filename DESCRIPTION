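Package: nscdyn
Title: Population Dynamics, Label Retention, and State Classification of
    Hippocampal Neural Stem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the lifelong maintenance of the hippocampal neural stem
    cell (NSC) pool as a dormant/resting/active compartment system with
    time-dependent activation rates, fitted to cohort time series by weighted
    least squares and ranked by AIC. Implements the label-retention statistics
    used to study return to quiescence (observed and disposable-model
    depletion rates, return-to-quiescence and dormant-activation fractions
    with Wilson intervals, and the resting/dormant decomposition of the
    proliferating pool), the H2B-GFP dilution division-counting procedure
    (corrected fluorescence, neighbor-normalized ratios, critical-bandwidth
    multimodality testing, and exact contingency comparison), and the
    single-cell G0/G1 and reporter-recombination classifiers. A synthetic
    cohort generator provides agent-based stochastic twins of the compartment
    model and every input table the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    minpack.lm,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
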
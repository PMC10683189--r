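Package: corac
Title: Convergence of Common and Rare Variant Gene-Level Association Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the convergence of gene-level association signals
    derived from common variants and from rare variants using chance-corrected
    agreement statistics (Cohen's kappa and Gwet's AC1) on the top-ranked
    genes after linkage-disequilibrium-block clumping, with bootstrap and
    Bayesian uncertainty. Includes a synthetic cohort generator with
    block-diagonal linkage disequilibrium and a frequency-dependent
    (selection-aware) effect-size model, gene-based association tests for
    common variants (correlated p-value aggregation) and rare variants
    (burden, SKAT and SKAT-O per annotation category), conditional
    (stratified) false discovery rates with stratified Q-Q summaries,
    profile-likelihood estimation of the selection exponent from summary
    statistics, and orchestration of simulation sweeps relating convergence
    to sample size, polygenicity and negative selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
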
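Package: psametab
Title: Serum NMR Metabolomics Discovery Pipeline for Psoriatic Arthritis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a serum 1H-NMR
    metabolomics discovery workflow for comparing psoriatic arthritis (PsA)
    patients with healthy controls (HC): intelligent spectral bucketing with
    residual-water exclusion and total-area normalization, Pareto scaling,
    OPLS-DA with 7-fold cross-validation, permutation validation and VIP
    variable selection, Mann-Whitney/Benjamini-Hochberg univariate testing,
    a multi-metabolite logistic ROC biomarker panel with Monte-Carlo
    cross-validation, Spearman correlation against the DAPSA clinical score,
    and hypergeometric metabolite-set over-representation with a pathway
    network. A calibrated synthetic-cohort generator (correlated truncated
    Gaussian concentrations, copula-linked DAPSA scores, rendered Lorentzian
    spectra with chemical-shift jitter) stands in for patient data so every
    stage of the pipeline is verifiable.
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
    MASS
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma
Config/testthat/edition: 3
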
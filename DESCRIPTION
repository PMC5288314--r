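Package: nmrfield
Title: Chemometric Detection of Metabolic Field Effects in 1H-NMR Tissue Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for 1H-NMR tissue metabolomics: simulation of
    frequency-domain spectra with class-specific metabolite effects and
    paired-subject structure, spectral preprocessing (reference alignment,
    spline baseline correction, region exclusion, segmental alignment, total
    area normalization, generalized-log transform), latent-variable modelling
    (PCA with Q-residual screening, orthogonal signal correction, NIPALS
    PLS-DA, multilevel PLS-DA for paired designs), validation machinery
    (Venetian-blinds and leave-one-out cross-validation, AUROC, cross-validated
    error rate, permutation testing, double cross-validation), and a
    Shapiro-gated univariate decision tree over tracked metabolite peaks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
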
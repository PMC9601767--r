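Package: afdisorder
Title: Intrinsic Disorder and Conditional Folding from Predicted Structure Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives per-residue intrinsic-disorder and conditional-folding
    (disordered-binding) predictions from AlphaFold-style predicted structure
    models. Three simple scores are computed from a model's per-residue pLDDT
    confidence (stored in the B-factor column) and its relative solvent
    accessibility (RSA): a pLDDT-based disorder score (1 - pLDDT), a
    window-smoothed RSA score with mirrored termini, and a piecewise
    combination of the two that flags accessible-yet-confident regions as
    candidate disordered binding sites. Solvent accessibility is computed with
    a built-in Shrake-Rupley sphere-sampling engine and normalised by
    Gly-X-Gly maximum accessibilities. The package also provides CAID-style
    benchmark evaluation (pooled Fmax, ROC AUC, coverage, fully-disordered
    calls), threshold and window calibration by F1 maximisation, and a
    synthetic-structure generator for end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
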
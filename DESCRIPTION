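Package: paracne
Title: Reverse Engineering of Tyrosine-Kinase Signaling Networks from
    Phosphoproteomic Spectral Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mutual-information based inference of kinase-substrate
    signaling networks from sparse, discrete phosphotyrosine spectral-count
    matrices. Implements iterative quantile discretization for tied,
    zero-inflated count vectors, a plug-in (bin-count) mutual information
    estimator with permutation-calibrated edge significance, data
    processing inequality pruning, bootstrap network consolidation, and
    Spearman sign annotation. Downstream, a single-tail enrichment engine
    (pVIPER) scores per-sample master-regulator kinases and synergistic
    kinase pairs against differential-phosphorylation signatures, and
    validation-side drug-combination statistics (Excess Over Bliss,
    Chou-Talalay combination index, IC50 interpolation, one-sided Fisher
    exact tests) are provided. A synthetic-data generator emulating
    LUAD-like phosphoproteomes makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
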
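Package: lmdhet
Title: Multi-Region Laser-Microdissection Proteomic Heterogeneity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of multi-region laser-microdissection
    (LMD) isobaric-label (TMT) proteomics experiments that profile enriched
    tumor epithelium, enriched stroma, and bulk tissue across spatially
    distinct sampling levels of a tumor specimen. Provides a PSM-level
    cohort simulator with planted ground truth, reporter-ion quantitation
    (PSM filtering, ratio-to-reference roll-up, median normalization,
    k-nearest-neighbor imputation), spatial heterogeneity statistics
    (MAD-based feature selection, correlation clustering, patient
    dendrograms, secreted-protein variance tests), empirical-Bayes
    moderated t-statistics with an all-patient sign-concordance filter,
    single-sample gene-set enrichment (ssGSEA) tumor/stroma admixture
    scoring, and cross-dataset / cross-platform comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    matrixStats,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
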
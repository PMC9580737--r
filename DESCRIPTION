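Package: gramscore
Title: Gram Stain Morphotype Scoring for Ovine Vaginal Inflammation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to develop, apply and validate Nugent-style Gram stain
    scoring systems for preclinical vaginal-product safety studies in the
    sheep model. Per-field bacterial morphotype and host-cell counts are
    converted to weighted threshold-rule scores; per-sample cytokine ELISA
    optical densities provide the inflamed/normal reference labels; and the
    full iterative development workflow is included: community-type
    stratified subsampling with distributional equivalence checks,
    two-sample t-test weighting with p-value bands, concordance, ROC AUC and
    Youden cut-off evaluation, logistic-regression sign diagnostics, and a
    seeded synthetic cohort generator so every stage can be exercised
    without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
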
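Package: bindspec
Title: Stage-Stratified Expression Statistics and Binding-Specificity
    Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two linked analyses from target-driven cancer drug
    discovery. The expression arm computes one-way ANOVA across tumor
    stages, planned stage contrasts, and label-permutation empirical
    p-values Pr(F > f_obs), stratified by patient group, plus exact
    two-by-two proportion tests. The screening arm implements a virtual
    screening cascade around a binding-site specificity statistic: SMILES
    ingestion and path fingerprints, Tanimoto similarity screening,
    rule-of-five filtering, docking-pose center-of-mass clustering into
    binding regions, and a per-compound specificity gap (difference
    between the two lowest per-region representative binding energies)
    with an empirical conditional-null significance test. A synthetic-data
    module generates expression matrices, compound libraries and docking
    pose tables with planted, recoverable structure for calibration and
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    withr,
    generics,
    ChemmineOB,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
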
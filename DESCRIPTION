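Package: dircor
Title: Directional Association Measures and Attenuation-Corrected Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the hidden directionality and deflation of
    the product-moment correlation between a narrow-scale ordinal variable
    (such as a test item) and a wider metric variable (such as a test score).
    Implements the product-moment and point-biserial correlations with
    population moments, the directional coefficient eta with an explicit sign
    convention, concordance-based ordinal measures (Goodman-Kruskal gamma,
    Somers delta in three directions, Kendall tau-b), maximal correlation
    under independent ordering, and the attenuation-corrected estimators
    R_AC and E_AC. A latent-variable discretization simulator reproduces the
    mechanical deflation of correlation caused by scale discrepancy, and a
    study pipeline summarises the eta1-eta2 discrepancy across category
    counts and category-ratio bins with standard effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
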
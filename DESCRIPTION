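Package: barcodegap
Title: Barcode-Gap Analysis and Evaluation of DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating DNA barcode (COI) reference libraries built
    from aligned sequences and specimen metadata. Computes Kimura 2-parameter
    pairwise distances with pairwise deletion, per-species barcode-gap
    statistics (maximum and mean intraspecific distance, nearest-neighbour
    distance, diagnosability), regional partition comparisons, nearest-neighbour
    and best-close-match identification tests of a query region against a
    reference region, refined-single-linkage (BIN-style) clustering with
    species-cluster concordance classification, and heteroscedastic mixed
    models with likelihood-ratio tests for distribution-category and dispersal
    effects. Includes a seeded K80 simulator that generates barcode libraries
    with realistic intra- and interspecific structure plus ground truth for
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    utils
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
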
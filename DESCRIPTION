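Package: cofnet
Title: Cofunctional Gene Network Construction by Log-Likelihood Evidence Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genome-scale cofunctional gene networks from heterogeneous
    evidence. Raw evidence scores (literature cocitation, coexpression,
    domain co-occurrence, phylogenetic profiles, gene neighborhood,
    protein-protein interactions) are benchmarked against an
    annotation-derived gold standard via binned log-likelihood scores,
    integrated with a rank-discounted weighted-sum rule, assessed against
    knockout-phenotype data (cumulative accuracy-coverage curves,
    leave-one-out ROC), and used for guilt-by-association prediction of
    pathway members and gene functions. Includes a seeded synthetic-data
    generator emulating every input class so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
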
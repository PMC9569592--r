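Package: fusionlab
Title: Clinical-Genomic Data Fusion for Cancer Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for fusing low-dimensional clinical data with
    high-dimensional gene-expression panels in binary cancer diagnostics.
    Extracts a single continuous malignancy-risk feature from discrete
    clinical variables via a Tabu-search-learned Bayesian network with
    likelihood-weighting inference and k-fold cross-fitting, quantifies
    clinical-molecular dependencies (Spearman correlation, Kraskov
    k-nearest-neighbour mutual information), and compares early-, late-
    and no-fusion strategies by bootstrap out-of-bag accuracy of a linear
    support vector machine under Wilcoxon rank-sum and ReliefF feature
    selection, together with Kuncheva feature-selection stability. A
    synthetic-data generator emulates the clinical and expression
    structure the analysis assumes, so the whole pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
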
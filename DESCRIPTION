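Package: pathmark
Title: Network-Constrained Pathway Biomarker Discovery from Case/Control Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies dysregulated pathways in case/control gene expression
    studies. Each pathway's activity is summarized per sample as the first
    principal component of its member genes' standardized expression; a
    condition-specific pathway interaction network is built from shared genes
    and cross-pathway protein-protein interactions, filtered by differential
    expression and co-expression evidence; and a connected set of pathway
    markers is selected by network-constrained greedy forward search scored
    with repeated cross-validated RBF-SVM AUC. Includes a gene-level t-test
    biomarker baseline and a latent-factor simulator of pathway-structured
    expression data with planted dysregulation for end-to-end validation.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
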
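Package: herbvec
Title: Activity-Vector Scoring and Clustering of Herbal Bioactivity Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-assay bioactivity profiling of herbal extracts
    on the percent-of-control scale (0 = maximal inhibition, 100 = no effect,
    >100 = enhancement). Reads herb-by-assay activity tables with per-cell
    provenance and herb character tables (Traditional Chinese Medicine nature,
    flavors, meridians, actions); summarises antioxidant and eicosanoid
    (5-LOX, COX-1, 12-LOX) inhibition profiles as Euclidean vector-magnitude
    scores; partitions herbs by k-means with a branch-and-bound exact solver
    for small panels; quantifies cluster-character association with exact
    tests and Benjamini-Hochberg adjustment; simulates labelled synthetic
    panels for recovery experiments; and orchestrates the whole analysis as a
    reproducible pipeline with scatterplot output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
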
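Package: twistmap
Title: Evolutionary Feature Selection and Auto Contractive Map Networks for
    Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements an end-to-end pipeline for mapping the joint structure
    of risk factors and genotypes in case-control studies: recoding of
    continuous, genotypic and binary variables into mutually exclusive binary
    indicator variables; a synthetic cohort generator with a liability-threshold
    disease model and planted ground truth; the TWIST protocol (evolutionary
    optimisation of a representative train/test split followed by evolutionary
    selection of a minimal predictive indicator subset, scored by a bank of
    learners on the held-out set); the Auto Contractive Map, an adaptive
    contraction network whose trained weight matrix is read as a variable
    similarity matrix; and similarity-network summaries built from it - the
    minimum spanning tree, its resampling-stability filter (Meta-MST), the
    maximally regular graph, and graph complexity indices (hubness H and
    topological entropy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    class,
    e1071,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
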
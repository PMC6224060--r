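Package: fdconnect
Title: Degree- and Distance-Weighted Resting-State Functional Connectivity Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds resting-state functional brain networks from per-subject
    correlation matrices using an edge-weighting model that combines node
    degree, inter-regional Euclidean distance and thresholded correlation
    (W_ij proportional to deg(i) deg(j) exp(-(eta D_ij - F_ij))). Implements
    the associated two-step thresholding procedure, group-level averaging
    over age/sex cohorts, a centrality index for selecting principal and
    secondary hub vertices of a representative graph, permutation-based
    male/female comparisons (sum-of-F multivariate statistic, Bonferroni-Holm
    familywise error control), and an average-based comparison against pure
    correlation weighting. Includes a latent-factor synthetic cohort
    generator with a default-mode-network-like community so the full
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    igraph,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
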
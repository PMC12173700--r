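Package: connectomediff
Title: Edge-Wise Permutation Contrasts and Structural-Functional Overlap
    for Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential connectome analysis for case-control cohorts with
    paired diffusion MRI (streamline-count) and resting-state fMRI
    (correlation) connectivity matrices on a shared parcellation. Implements
    an edge-wise permutation variant of the Network Based Statistic
    (Mann-Whitney tests per edge with per-edge permutation nulls), Rosenthal
    effect sizes, subnetwork extraction with eigenvector-centrality hub
    detection, a node-identity permutation test for structural-functional
    subnetwork overlap, permutation-FDR clinical correlations, and a
    synthetic cohort generator with planted effects for end-to-end
    validation. All results are returned as tibbles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
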
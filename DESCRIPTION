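Package: snapdyn
Title: Reconstructing Gene-Expression Dynamics from Pairwise Single-Cell
    RNA FISH Snapshots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct real-time gene-expression dynamics
    (cycles and stochastic switches) from pairwise single-cell snapshot
    mRNA measurements such as RNA fluorescence in situ hybridization
    (FISH) counts.  Provides synthetic-data simulators for the continuous
    and bursty transcription regimes, maximum-likelihood estimation of
    harmonic mean-expression trajectories and of burst-probability cycles
    and switches, principal-component analysis of the between-gene
    covariance with iterative diagonal completion, identifiability
    (degrees-of-freedom) accounting, and cluster-synchrony statistics
    with phase-randomization significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
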
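Package: mdrnet
Title: Methylation-Driven Gene Networks from MeRIP-Seq Differential
    Methylation and Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts m6A-driven genes (mDrGenes) and their consensus
    interaction network (mDrNet) by integrating per-replicate-set
    differential m6A methylation gene calls with a protein-protein
    interaction network. Each differentially methylated gene seeds a
    Random Walk with Restart on the network; candidate interactors are
    assessed against a degree-conditioned empirical null built from
    degree-preserving random networks and a shortest-path rule, and
    significant seed-candidate interactions recurring across all
    replicate sets form the consensus network. Includes a synthetic
    study generator with planted ground truth, broom-style tidiers,
    ggplot2 plots, and a command-line pipeline driver.
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
    igraph,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
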
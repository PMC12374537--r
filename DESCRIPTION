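Package: recombinr
Title: Recent Homologous Recombination in Bacterial Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies recent homologous recombination among
    bacterial genomes from gene-level comparisons. Computes reciprocal best
    matches (RBMs) between genomes, gene-based average nucleotide identity
    (ANI), and the F100 statistic (fraction of identical RBM genes) together
    with a gamma-Poisson no-recombination null expectation and an exact
    excess test. Calls recently exchanged genes between genomes of different
    genomovars, summarises recombinant tracts, spatial randomness and an
    empirical r/m ratio, clusters genomes into nested ANI tiers (genomovar,
    phylogroup, species), detects ANI gaps between species, scans for gene
    sweeps via allele partitions, and builds neighbour-joining trees for
    incongruence analysis. Includes a population simulator with
    machine-readable ground truth that emulates the statistical structure of
    single-cell amplified genome (SAG) collections, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    igraph,
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
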
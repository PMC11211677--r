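Package: pantnfit
Title: Pangenomic Tn-Seq Fitness Analysis and Cofitness Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of mariner (Himar1) transposon insertion sequencing
    (Tn-seq) data across multiple related bacterial strains. Locates TA
    dinucleotide target sites, builds per-gene insertion count tracks from
    wig files or mapped coordinates, and calls gene essentiality by three
    independent routes: a four-state hidden Markov model with geometric
    emissions (essential / growth-advantage / nonessential /
    growth-disadvantage), a Bayesian classifier built on the Gumbel
    extreme-value null for the longest insertion-free run of TA sites, and
    a Monte Carlo pseudodataset fitness estimator (log2 fold change of
    observed versus expected insertion abundance). Cross-strain core-gene
    fitness matrices assembled from orthogroup tables feed a Pearson
    cofitness network thresholded by the random-matrix-theory transition
    from Wigner to Poisson eigenvalue-spacing statistics, with node-level
    topology metrics, module detection, and enrichment statistics (Fisher's
    exact test, permutation Z test, Tukey HSD). A synthetic pangenome and
    mutant-library generator with planted ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
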
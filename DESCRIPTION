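Package: phagephylo
Title: Whole-Genome Phylogenomics, Genome Structure and Growth Kinetics for Bacteriophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for placing newly sequenced bacteriophages among their
    relatives from whole-genome sequence alone, together with the laboratory-side
    growth statistics that round out a phage description. Provides detection of
    collapsed long terminal repeats from read-coverage profiles, tandem-repeat
    scanning, consensus gene calling across multiple predictor tracks, a seeded
    ungapped local-alignment engine with Karlin-Altschul significance (nucleotide
    and six-frame translated modes), fragmented whole-genome translated similarity
    matrices, similarity-network clustering with force-directed layout,
    neighbor-joining phylogenomics with patristic group-separation statistics,
    maximum-agreement-subtree congruence testing with a Monte-Carlo null, and
    estimators for phage adsorption rate, latent period and burst size from titre
    series. A synthetic-data module generates modular phage genome communities,
    collapsed assemblies with shotgun coverage, marker protein families evolved on
    a known tree, gene-predictor tracks with controlled error, and noisy titre
    series, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    seqinr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    mclust,
    optparse,
    rmarkdown,
    S4Vectors,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
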
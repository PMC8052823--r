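Package: censat
Title: k-mer Based Quantification of Centromere Satellite Copy Number and
    Sequence Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates the copy number and within-genome sequence
    heterogeneity of tandem satellite repeats (such as the house mouse
    120-bp minor and 234-bp major centromere satellites) directly from
    whole-genome shotgun reads, without an assembly. Reads are decomposed
    into canonical k-mers, counts are corrected for library GC bias with a
    LOESS model fitted on unique reference k-mers, and satellite copy
    number is estimated from the median normalized frequency of the
    consensus repeat's constituent k-mers. Within-genome repeat
    heterogeneity is summarised by a centromere diversity index (average
    pairwise differences between reads anchored to the same consensus
    position and strand) and by a positional polymorphism matrix built
    from relaxed-Hamming-distance k-mers. Phylogenetic heritability of
    satellite metrics is estimated under a Brownian-motion model with a
    permutation null. A synthetic-data generator produces tandem-array
    genomes and GC-biased reads with known ground truth for every
    estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
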
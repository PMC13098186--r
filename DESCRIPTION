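Package: cacensus
Title: Census of Microbial Carbonic Anhydrase Gene-Family Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for surveying carbonic anhydrase (CA)
    gene-family diversity across microbial genomes and metagenomes. Provides
    quality filtering of putative CA proteins, greedy identity-threshold
    clustering, center-star alignment and profile-model construction, profile
    scanning of metagenome ORF sets with best-hit assignment,
    lowest-common-rank taxonomic conservation statistics, genome
    presence/copy-number census and class co-occurrence tables,
    environment-scaled abundance and specificity summaries, and
    support-based tree collapsing with phylogenetic-diversity randomization
    tests. A synthetic-data generator with known ground truth makes every
    stage testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    picante,
    optparse
Config/testthat/edition: 3
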
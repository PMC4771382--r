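Package: islandscan
Title: Detection of Genomic Islands of Differentiation Between Ecotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting genomic islands of differentiation between
    recently diverged ecotypes from SNP data. Implements inbreeding-aware
    locus-by-locus AMOVA F-statistics, an F_ST outlier test against a
    coalescent null simulated under a hierarchical island model with
    per-population inbreeding, hidden-Markov-model segmentation of
    genome-ordered outlier z-scores into islands with region-level false
    discovery rate control, classification of islands by parallel
    habitat-associated allele frequency change, and downstream context
    analyses: Ripley's K clustering of outlier SNPs on the genetic map,
    recombination-rate estimation from a genetic map by smoothing splines,
    windowed nucleotide diversity contrasts, and permutation tests for
    co-localization of islands with quantitative trait loci. A synthetic-data
    generator emulating a six-deme, three-group lake-stream sampling design
    makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
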
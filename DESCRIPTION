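Package: songculture
Title: Quantitative Analysis of Inter-Population Transmission of Humpback
    Whale Song
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how accurately song patterns are learned
    when they are transmitted between humpback whale populations. Implements
    the Levenshtein-distance similarity index (LSI) on hierarchical song
    sequences (units, phrases, themes, song cycles), weighted by acoustic
    unit similarity; average-linkage hierarchical clustering of LSI matrices
    with bootstrap cluster support and cophenetic correlation validation;
    PCA-based composite song complexity scores; exact Mann-Whitney rank-sum
    comparisons between populations; theme occupancy (shared versus
    population-unique themes) tallies; and a seeded generator of synthetic
    two-population song cultures (evolutionary and revolutionary song change
    with a transmission lag and acoustically biased copy error) for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    mclust,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
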
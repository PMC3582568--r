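Package: clamir
Title: Small RNA Sequencing Analysis for Plant miRNA Discovery and
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for plant small-RNA sequencing studies,
    developed around the grafted-watermelon (Citrullus lanatus) use case:
    adapter trimming and read collapsing, RNA-class annotation with a fixed
    precedence, known-miRNA identification by bounded-mismatch matching,
    novel-miRNA calling from hairpin secondary structure using six structural
    criteria and the minimal folding free energy index (MFEI), penalty-scored
    complementarity target prediction, and count-based differential expression
    (Audic-Claverie, Fisher exact and chi-squared 2x2 tests) between
    libraries. Includes a seeded synthetic-data generator with recorded truth
    for recovery benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    methods,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
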
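Package: ecvmate
Title: Expected Cross Value Optimization for Genomic Mate Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing crossing blocks in breeding programs with the
    expected cross value (ECV), the expected number of desirable alleles in a
    gamete produced by the progeny of a candidate parent pair. Implements the
    Markov model of meiotic inheritance (recombination-frequency chain),
    closed-form ECV for single and multiple traits, the predicted cross value
    (PCV) by exact dynamic programming, integer-programming mate selection with
    a genomic-relationship (inbreeding) constraint and iterative conflict
    constraints, lexicographic multi-trait optimization with degradation
    tolerances, VanRaden genomic relationship matrices, ridge-regression BLUP
    genomic prediction baselines, and a stochastic breeding-program simulator
    for benchmarking selection strategies over generations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
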
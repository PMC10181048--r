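Package: siig
Title: Selection Index of Ideal Genotype for Multi-Trait Genotype Ranking
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks crop genotypes by their closeness to a trait-wise ideal
    genotype.  Trait columns of a genotype-by-trait matrix are vector
    normalized to unit Euclidean norm, per-trait ideal and non-ideal profiles
    are taken as the directed extrema (larger-is-better for benefit traits
    such as grain yield, smaller-is-better for cost traits such as days to
    maturity), and each genotype is scored by the closeness coefficient
    d-/(d+ + d-) of its Euclidean distances to the two profiles.  The score
    lies in [0, 1] with 1 the ideal genotype, is free of trait units, and
    needs no trait weights.  Includes score-based grouping and threshold
    selection, Pearson correlation reports with significance stars, delimited
    table input/output, a bundled multi-environment barley trial dataset, a
    synthetic trait-matrix generator with controlled correlation structure,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
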
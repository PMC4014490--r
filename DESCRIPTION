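Package: gxsmap
Title: Gene-by-Sex Interaction QTL Mapping in Heterogeneous Stock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene-by-sex (GxS) and gene-by-gene (GxG) interaction
    quantitative trait loci in multiparental outbred populations such as
    heterogeneous stock (HS) mice. Provides a Bayesian sparse-partitioning
    mapper (Markov chain Monte Carlo over partitions of a small selected
    predictor set into interacting groups), a frequentist comparator based on
    bootstrap resample model averaging over forward-selected multiple-QTL
    regressions on founder-ancestry dosages (resample model inclusion
    probabilities, RMIP), allelic-correlation kinship with single-component
    REML heritability, cross-validated decomposition of the phenotypic
    variance attributable to GxS interactions, permutation-based false
    discovery calibration, and a synthetic HS population generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
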
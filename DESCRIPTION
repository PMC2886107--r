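Package: proteopop
Title: Population Proteomics of Triplex-Labelled Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-level analysis of quantitative proteomics
    experiments that use triplex isotopic labelling in a constrained randomized
    incomplete block design. Provides a D-type criterion and exchange optimizer
    for assigning colony replicates to triplex blocks and labels, assembly of
    peptide-spectrum matches into parsimonious protein groups with decoy-based
    FDR estimation, two-stage (block-centering and per-label median/MAD)
    normalization, per-protein linear mixed-effects estimation of population
    effects with one-sided P-value profiles, representation-factor overlap and
    hypergeometric term-enrichment statistics, self-organizing tree (SOTA)
    clustering of P-value profiles, and quadratic regression of pathway-level
    effects against absolute latitude. A synthetic-data generator reproduces
    the statistical structure the pipeline assumes so every stage can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
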
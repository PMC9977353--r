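Package: resilprot
Title: Quantitative Genetics of the Plasma Proteome for Disease Resilience
Version: 0.1.0
Authors@R:
    person("resilprot", "maintainers", email = "resilprot@example.org",
           role = c("aut", "cre"))
Description: Tools to link plasma-proteome abundances measured in young pigs
    by isobaric (TMT) labelling to later performance and disease-resilience
    phenotypes. Implements reference-channel normalization of log2 protein
    abundances with a per-protein mixed model, genomic-relationship-matrix
    construction (VanRaden method 1, optionally blockwise by breeding
    company), average-information REML for heritability and bivariate genetic
    correlations with boundary-aware likelihood-ratio tests and
    Benjamini-Hochberg FDR, phenotypic association scans including a reverse
    mixed linear model for binary traits, signed preranked gene-set
    enrichment with permutation FDR, and ward.D clustering of enrichment
    profiles. A synthetic-data generator reproduces the statistical structure
    of a multi-plex TMT disease-challenge study (run-confounded missingness,
    litter and batch effects, liability-threshold binary traits, controlled
    protein-trait genetic correlations) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
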
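Package: sbturnover
Title: Turnover and Magnitude of Sex-Biased Gonadal Expression Across a
    Four-Species Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the evolution of sex-biased gene expression in
    gonads across a fixed four-species phylogeny. Calls per-gene, per-species
    sex-bias status (testis-biased, ovary-biased, unbiased) from testis/ovary
    RNA-seq counts with a two-fold rule, an exact binomial differential
    expression test and median library normalization; classifies each gene's
    four-species status profile into clade-wide, lineage-specific transition
    (LST), ingroup-conserved and multiple-transition classes; computes
    standardized lineage-specific transition rates (S-LSTs) per branch and
    transition category with chi-squared contrasts; analyses how fold
    sex-bias grows with conservation age; relates transitions to expression
    breadth (pleiotropy) across 17 tissues; and contrasts branch dN/dS across
    expression categories after saturation filtering. Includes a seeded
    synthetic-data generator with planted ground truth so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
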
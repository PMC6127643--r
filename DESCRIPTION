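Package: fecalconcord
Title: Concordance Evaluation of Fecal Collection Methods for Microbiome
    and Metabolomics Studies
Version: 0.1.0
Authors@R: person("Concordance", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to score alternative fecal collection methods against a
    designated gold standard (immediate freezing) in paired study designs.
    Implements alpha-diversity indices (Shannon, Gini-Simpson, bias-corrected
    Chao1), Bray-Curtis distances, principal coordinates analysis,
    Kruskal-Wallis and PERMANOVA group tests, one-way ANOVA intraclass
    correlation coefficients with subject-level bootstrap confidence
    intervals, a distance-based ICC for beta-diversity, metabolomics
    preprocessing (detectability filtering, overlap accounting, half-minimum
    imputation, quantile normalization, log10 transform), Spearman screens
    between genera and short-chain fatty acids with Bonferroni control, and
    a synthetic paired-design data generator with known variance-component
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vegan
Suggests:
    testthat (>= 3.0.0),
    limma,
    biomformat,
    optparse
Config/testthat/edition: 3
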
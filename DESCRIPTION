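Package: streamgut
Title: Variance Partitioning of Freshwater Macroinvertebrate Gut Microbiome
    Beta Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for 16S amplicon surveys of freshwater
    macroinvertebrate gut microbiomes sampled across stream sites. Curates
    ASV count tables, collapses them to the family level, rarefies with
    replication, and computes alpha diversity (observed taxa, bias-corrected
    Chao1, Shannon) with non-parametric group tests, Bray-Curtis beta
    diversity, NMDS ordination, PERMANOVA and PERMDISP permutation tests,
    and Kruskal-Wallis indicator-taxon screening with false discovery rate
    control. Its core is a Bayesian hierarchical Beta regression with a
    logit link that partitions pairwise Bray-Curtis dissimilarity among
    functional feeding group, stream site, host family, and host genus via
    varying intercepts, with model comparison by WAIC, Bayesian R-squared,
    posterior predictive summaries per group level, and convergence
    diagnostics. A seeded synthetic-data module generates metadata, count
    tables, and model-structured dissimilarity observations with known
    ground truth so every stage is testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    pracma,
    optparse
Config/testthat/edition: 3
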
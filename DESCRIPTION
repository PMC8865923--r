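Package: dermadiv
Title: Spatial-Temporal Analysis of Skin Bacterial Communities from ASV Tables
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for amplicon sequence variant (ASV) community
    analysis of longitudinal tape-strip skin-microbiome studies. Implements
    negative-control contaminant filtering, prevalence and taxonomy filters,
    fourth-root relative-abundance normalization, alpha- and beta-diversity
    (ASV richness difference, Jaccard membership, Yue-Clayton similarity),
    permutational multivariate analysis of variance (PERMANOVA) with
    restricted (strata-aware) permutations built from first principles,
    within-participant persistence profiling, core- and ubiquitous-community
    identification, and the supporting statistical primitives
    (Kruskal-Wallis, paired t, Benjamini-Hochberg FDR, linear and
    random-intercept models). A hierarchical study simulator with ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    biomformat
Config/testthat/edition: 3
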
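Package: hindval
Title: Blocked Indicator Species and Diversity Analysis for Gut
    Microbiota Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis of compartmentalised gut microbial communities from
    blocked (animal x body-site) 16S rRNA survey designs. Provides
    taxonomic rank collapse with unclassified-rank fallback labels,
    rarefaction, Shannon alpha diversity with pairwise Kruskal-Wallis
    tests, Bray-Curtis beta diversity with principal coordinates analysis,
    PERMANOVA with free, within-block and exhaustive within-block
    permutation schemes, multivariate dispersion testing, and an indicator
    value (IndVal) analysis for single body sites and combined site groups
    with blocked Monte-Carlo randomization and Benjamini-Hochberg false
    discovery rate control. Includes a Dirichlet-multinomial synthetic
    community generator that emulates a blocked equine hindgut study
    design with planted indicator taxa.
License: MIT
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
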
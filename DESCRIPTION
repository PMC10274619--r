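Package: elevzone
Title: Dissimilarity-Based Detection of Elevational Zonation in Species Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether proposed altitudinal boundaries correspond to real
    breaks in species composition along elevational gradients. Provides
    occurrence-record curation (coordinate cleaning, deduplication, taxonomic
    harmonization, entity assignment), 200-m elevational banding, Jaccard-family
    beta-diversity partitioning into turnover and richness-difference
    components, UPGMA clustering of elevation bands, gap-statistic selection of
    the number of elevational groups, bootstrap (clusterwise Jaccard) cluster
    support, and spanned-range statistics for candidate boundary elevations.
    Includes a synthetic occurrence generator with planted zonation so that
    every pipeline stage can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    vegan,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
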
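Package: bioregionize
Title: Occurrence-Based Marine Bioregionalization from Gridded Incidence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delineating marine bioregions and bioprovinces from
    georeferenced species occurrence records. Implements the full analysis
    chain: cleaning of raw occurrence tables (open-nomenclature qualifiers,
    synonym reconciliation, coordinate validation), aggregation onto 5-degree
    latitude-longitude grid cells, occurrence-based (Hurlbert) rarefaction for
    sampling-completeness assessment, two-stage agglomerative clustering of
    Jaccard dissimilarities with elbow and silhouette diagnostics, a bipartite
    cluster-species network with a force-directed layout and a
    community-consensus check, and translation of cluster groupings into a
    bioregion/bioprovince scheme with contiguity-based outlier reassignment and
    per-unit richness, species/genus ratio and endemism indices. A synthetic
    occurrence-world generator with planted provinces and configurable noise
    provides ground-truthed data for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    igraph,
    mclust,
    geosphere,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    cluster,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
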
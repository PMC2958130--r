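Package: evoccur
Title: Expression Variation Occurrence Analysis for Paired Two-Condition
    Microarray Data
Version: 0.1.0
Authors@R:
    person("evoccur", "maintainers", email = "maintainers@evoccur.org",
           role = c("aut", "cre"))
Description: Implements occurrence-based selection of differentially
    expressed genes from paired two-condition expression data measured on
    several donors. A per-donor Expression Variation (EV) statistic is
    computed by positioning each gene in a Box-Cox transformed
    intensity/difference plane relative to cubic-spline confidence bands
    fitted to the intensity-dependent dispersion of the data. Genes are
    then selected by how often (in how many donors) they exceed an EV
    threshold in the same regulation direction, with combined p-values per
    occurrence level. Focus-gene interaction networks are built on a
    user-supplied knowledge graph and scored with hypergeometric tail
    probabilities; network structuring metrics drive an iterative
    optimizer that recommends the occurrence stringency threshold.
    Inter-individual variability is decomposed into technical and
    biological components with projected gene counts across occurrence
    levels. Seeded synthetic-data generators emulate cohorts, interaction
    graphs and gene sets with the statistical structure the method
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
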
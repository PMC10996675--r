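Package: crossome
Title: Cross-Ome Lipid-Protein Fingerprinting of Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular fingerprinting of genotype panels profiled on
    matched proteomic and lipidomic layers. Computes the lipid-by-protein
    Kendall tau-b cross-correlation matrix with pairwise-complete handling of
    missing intensities, applies a connectivity retention filter, clusters both
    axes (hierarchical ordering plus k-means assignments), tests clusters for
    enrichment of Gene Ontology Cellular Component terms and lipid classes with
    one-sided Fisher's exact tests under Benjamini-Hochberg control, aggregates
    per-genotype cluster and gene-set log2 fold-change signatures, extracts
    bipartite lipid-protein association networks, ranks top correlated partners,
    and flags genotype outliers with robust z-scores. Includes a lipid shorthand
    nomenclature parser (class, chain carbons, double bonds, ether and sphingoid
    features) and a synthetic panel generator with planted cross-ome modules,
    replicate noise, and intensity-dependent missingness so that the entire
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
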
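Package: herdnet
Title: Intra-Breed Genetic Diversity and Animal-Exchange Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Herd-level characterization of intra-breed genetic diversity in
    livestock from microsatellite genotypes combined with animal-exchange
    networks between herds. Provides microsatellite diversity statistics
    (heterozygosities, Fis, rarefied allelic richness, exact Hardy-Weinberg
    tests, null-allele screening), Weir-Cockerham Fst with jackknife standard
    deviations, Reynolds coancestry distances between herds, admixture-model
    Bayesian clustering with Evanno delta-K model selection and herd-level
    genetic-group assignment, exchange-network metrics (average degree,
    shortest-path-length matrices, geodesic counts, SPL-stratified summaries),
    the Mantel correlation between genetic and network distances, tiered
    cryobank donor prioritization, and a forward-time drift-on-network
    simulator for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
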
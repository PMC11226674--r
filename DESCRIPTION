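Package: betaregion
Title: Phylogenetic Turnover, Biogeographic Regionalization and Map Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative biogeographic regionalization from assemblage data.
    Computes taxonomic and phylogenetic Simpson turnover (Tbsim/Pbsim) from a
    cell-by-taxon presence matrix and a (posterior set of) phylogenies,
    delineates hierarchical biogeographic regions and realms by agglomerative
    clustering with elbow-based cluster selection and spatial validity rules,
    ordinates assemblages by nonmetric multidimensional scaling rotated to
    geography, and compares independent regionalizations with the area-weighted
    V-measure against Voronoi randomization null models. Includes a synthetic
    assemblage simulator with planted spatial regions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    mclust,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
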
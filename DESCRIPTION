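Package: RaoFacets
Title: Multi-Facet Diversity Partitioning with Rao Quadratic Entropy and
    Environment-Space Attribution
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Partitions taxonomic, functional and phylogenetic diversity of
    presence/absence plant communities into Jost-corrected Rao quadratic
    entropy alpha and pairwise proportional beta components; quantifies
    phylogenetic signal of species traits with Blomberg's K (permutation
    test) and Pagel's lambda (likelihood-ratio test); builds spatial
    predictors by principal coordinates of neighbour matrices (PCNM) and
    spatial correlograms (Moran's I, Mantel); and attributes diversity
    variation to environmental versus spatial drivers through
    forward-selected redundancy analysis and two-set variation
    partitioning on adjusted R-squared. Includes a synthetic community
    generator (Yule phylogenies, lambda-scaled Brownian traits, Gaussian
    process landscapes, niche- and dispersal-based assembly) so that every
    stage of the pipeline is testable with known statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    MASS
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    phytools,
    geosphere,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
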
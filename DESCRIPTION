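Package: migsurf
Title: Effective Migration and Diversity Surfaces from Georeferenced Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers spatially heterogeneous effective migration and
    effective diversity surfaces from georeferenced SNP genotypes on a
    triangular deme grid. Observed pairwise genetic dissimilarities are
    modelled through resistance distances on the deme graph with a
    matrix-variate (Wishart) likelihood; piecewise-constant rate surfaces
    are represented by Voronoi tessellations with a variable number of
    tiles and sampled by reversible-jump Markov chain Monte Carlo.
    Includes posterior summaries (mean surfaces, trough and corridor
    consensus), Bayes factors against a uniform-migration null via power
    posteriors, genotype panel preparation filters, PCA-based model
    comparison, Weir-Cockerham FST, partial Mantel tests, and a
    stepping-stone Wright-Fisher simulator for generating synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
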
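Package: primacyhull
Title: Primacy Coding Model and Olfactory Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for the primacy model of concentration-invariant odor
    identity coding. Implements mass-action receptor activation for pure
    odorants and mixtures, primacy sets, and the primacy hull: the
    simplicial complex of high-affinity receptor sets traced out by
    sweeping mixture directions through a low-dimensional space of
    receptor affinities. Provides analyses of glomerulus-to-Kenyon-cell
    connectivity (Pearson similarity matrices, degree-preserving
    checkerboard nulls, PCA and Isomap embeddings, cross-animal Procrustes
    alignment), enrichment tests of Kenyon-cell inputs for high-affinity
    "primacy" receptor sets with false discovery rate control, and a
    surrogate-data generator that plants a shared primacy hull in paired
    affinity and connectivity data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
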
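Package: pocketmap
Title: Ligand-Independent Binding Site Detection, Comparison and Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for mapping potential small-molecule binding
    sites on protein structures. Detects surface cavities geometrically with
    alpha spheres derived from the Delaunay complex of protein heavy atoms,
    converts cavities (or bound ligands) into pharmacophore-typed surface
    patches, aligns and scores patch pairs by Gaussian shape and color overlap
    on a 0-4 PatchScore scale, evaluates retrieval performance (AUROC,
    enrichment factor, BEDROC), and clusters all-against-all similarity
    matrices into binding-site maps (conservation filtering, average-linkage
    hierarchical clustering, DBSCAN, Circos-compatible link exports). Includes
    a deterministic synthetic pocket-protein generator so the full pipeline is
    testable without external structure databases, and a parser for fpocket
    output directories for interoperability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
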
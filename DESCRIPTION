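Package: biogps
Title: Alignment-Free Comparison and Clustering of Enzyme Active Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Describes enzyme active sites by probe interaction fields
    condensed into four-point geometric fingerprints (quadruplets),
    compares sites all-against-all through Gaussian volume-overlap
    Tanimoto scores, and clusters or projects structures with principal
    component analysis of their similarity profiles. Includes catalytic
    machinery superposition via the iterative Horn quaternion fit with
    automatic mirror-image handling, LIGSITE-style pocket detection on a
    3D lattice, a deterministic synthetic-pocket generator for offline
    validation, and a one-command pipeline from PDB structures to a
    2-D cluster map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
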
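Package: pubshape3d
Title: Conformer Models, Gaussian Shape Similarity and 3-D Neighboring
    for Small Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bounded conformer models for small organic molecules and
    compares them in three dimensions. Implements coverage rules deciding
    which molecules receive a conformer model, a size/flexibility-driven
    RMSD sampling rule with symmetry-aware heavy-atom RMSD clustering,
    Gaussian (Grant-Pickup) analytic shape volumes, steric multipole
    moments and principal-steric-axes canonicalization, rigid-body
    superposition optimization yielding shape and pharmacophore-feature
    (color) Tanimoto scores, diverse conformer ordering, shape
    fingerprints with alignment recycling, 64-bit global conformer
    identifiers, and a "similar conformers" neighboring engine with
    score matrices and single-linkage clustering. Reads and writes
    multi-record V2000 SDF with a documented property-tag dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
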
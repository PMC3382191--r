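Package: phoreseed
Title: Receptor-Based 3D Pharmacophore Construction, Screening and
    Binding-Pocket Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds receptor-structure-based 3D pharmacophore models from
    protonated receptor-ligand complexes: typed interaction features
    (hydrogen-bond donor/acceptor, cation, aromatic ring) seeded at ligand
    annotation points, plus excluded volumes centred on binding-site
    hydrogen atoms and aromatic ring centroids.  Screens multi-conformer
    ligand ensembles against a model by correspondence search, Kabsch
    rigid-body superposition, feature-tolerance and excluded-volume clash
    tests, and summarises screens as per-ligand hit tables.  Includes
    radius-map tuning against labelled active/inactive libraries, a
    grid flood-fill binding-pocket volume estimator, residue conservation
    mapping from pairwise alignments, Ballesteros-Weinstein numbering,
    key-interaction geometry reports, and a synthetic-data generator that
    plants toy complexes and ensembles with known hit/miss ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
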
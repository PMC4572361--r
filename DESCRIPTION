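Package: fmct
Title: Ligand-Based Protein Target Prediction from Bioactivity Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Find My Compound's Targets (FMCT): proposes protein targets
    for query compounds by locating chemically similar compounds in a
    curated bioactivity reference table and transferring their annotated
    targets. Implements curation of BindingDB-style affinity dumps
    (Ki/IC50 filtering, range-qualifier removal, structure sanitization),
    fingerprint generation (an in-package Daylight-style subgraph-hash
    path fingerprint, circular and topological-torsion fingerprints,
    plus OpenBabel and atom-pair families), Tanimoto/Dice/Cosine
    similarity with correlation-based selection of least-redundant
    metrics, maximum-common-substructure similarity with fragment-
    tolerant matching, UniProt-merged target reports for single and
    batch queries, clustering-based reference-set reduction, a thin
    RESTful web-service client, and a seeded synthetic-fixture
    generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ChemmineR,
    ChemmineOB,
    jsonlite,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
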
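Package: idranno
Title: Function Annotation Transfer and Consensus Tracks for Intrinsically
    Disordered Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for annotating intrinsically disordered protein regions
    (IDRs). Transfers Gene Ontology and IDPO function terms from curated
    reference regions to predicted IDRs by distance-weighted k-nearest-
    neighbour voting over mean-pooled protein-language-model residue
    embeddings, with true-path propagation over the ontology DAG and
    CAFA-style region-level f-max evaluation. Also computes merge, majority
    and strict consensus disorder tracks from multiple per-residue
    annotation sources, and labels IDRs as compact or expanded from the
    apparent Flory scaling exponent. Includes a seeded synthetic-fixture
    generator so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
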
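Package: rna3wj
Title: Dual-Resolution Graph Attention Modelling of RNA Three-Way Junction Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the three inter-branch angles of RNA three-way junctions
    directly from sequence and pseudoknot-free secondary structure. Builds a
    fine-grained nucleotide graph and a coarse-grained tree graph (loops as
    nodes, helical stems as edges), fuses the two resolutions with a gated
    attention network, and regresses angles via a periodic sine/cosine
    parameterization. Also extracts ground-truth angles from 3D structures
    (C4' backbone anchors, junction incenter construction), reconstructs and
    scores rigid-star junction skeletons, and ships a synthetic-data generator
    that plants recoverable geometry so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    Matrix,
    igraph,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
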
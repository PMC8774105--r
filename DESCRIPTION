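Package: metbridge
Title: Methionine-Aromatic Bridge Clusters in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and geometric analysis of methionine-aromatic
    "n-bridge" clusters in protein structures. Reads PDB and mmCIF
    coordinate files, finds Met-aromatic contacts under a distance
    criterion (6.0 Angstrom default, no angular filter), enumerates
    bridge clusters (one methionine surrounded by n aromatic residues)
    on a bipartite residue interaction graph, maps aromatic ring
    centroids into a canonical Met-centered frame with a two-quaternion
    construction, and aggregates survey statistics: cluster composition,
    enzyme-class breakdown, distance histograms and B-factor context.
    Includes a synthetic structure generator that plants clusters at
    known geometry so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
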
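Package: rcc3d
Title: Residue Cluster Class Fingerprints from Protein 3D Structures
Version: 1.0.0
Authors@R:
    person("RCC3D", "Developers", email = "rcc3d@example.org",
           role = c("aut", "cre"))
Description: Computes residue cluster class (RCC) representations of protein
    three-dimensional structures. From atomic coordinates in PDB format it
    builds a residue contact graph at a configurable distance threshold
    (accelerated by a 3D grid hash and per-residue bounding-sphere pruning),
    enumerates maximal cliques with a pivoted Bron-Kerbosch search under a
    degeneracy ordering, and counts maximal cliques of size 3 to 6 in 26
    sequence-adjacency classes, yielding a 26-dimensional feature vector per
    structure suitable for structural and functional machine learning. Includes
    brute-force oracles for every stage, synthetic structure and random-graph
    generators for self-contained testing, a batch driver over multiple
    distance cutoffs and side-chain settings, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
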
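Package: flatrank
Title: Ranks of Flattening Matrices under the General Markov Model on Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constructing flattening matrices (unfoldings) of
    site-pattern probability tensors arising from the general Markov model
    of sequence evolution on a phylogenetic tree, and for verifying the
    identity between the rank of a flattening for a vertex bipartition A|B
    and r raised to the minimum vertex cut separating A from B.  Includes
    Sankoff-style parsimony length with clamped internal vertices,
    max-flow/min-cut certificates for edge and vertex cuts, exact rank
    certification by Gaussian elimination over a prime field for rationally
    specified parameters, SVD split scores, SPR and TBR neighbourhood
    enumeration with breadth-first certification of split distances, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
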
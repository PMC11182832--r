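Package: netvardim
Title: Dimensions of Group-Based Models on Level-1 Phylogenetic Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Algebraic machinery for group-based Markov models of sequence
    evolution on level-1 (galled-tree) semi-directed phylogenetic networks.
    Builds the Fourier-coordinate parameterization of any model (G, B) given
    by a finite abelian group G and a subgroup B of its automorphism group,
    computes the dimension of the associated phylogenetic variety by exact
    generic Jacobian rank over prime fields, derives tropical lower-bound
    certificates from weight vectors, evaluates closed-form expected
    dimensions and deficiencies, glues networks along cut edges via toric
    fiber products, and runs dimension-based distinguishability tests for
    pairs of networks.  Includes readers and writers for extended Newick
    with hybrid nodes and a JSON edge-list dialect, sunlet and random
    level-1 network generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
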
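Package: mulfold
Title: Polyploid Phylogenetic Networks from Multilabeled Gene Trees
Version: 0.1.0
Authors@R:
    person("The mulfold", "Authors", email = "mulfold@example.org",
           role = c("aut", "cre"))
Description: Estimates a rooted polyploid species phylogeny (a phylogenetic
    network) from a collection of possibly multilabeled rooted gene trees
    under incomplete lineage sorting. Gene trees are decomposed into
    cluster-multiplicity records; a maximum-weight approximately-compatible
    subset is selected exactly by branch-and-bound; a greedy consensus
    MUL-tree is assembled and refined to binary; and the MUL-tree is folded
    into a network by merging near-isomorphic clades under a tree edit
    distance threshold. Includes a multispecies-coalescent simulator on
    species MUL-trees, topological distances for MUL-trees and networks,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
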
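Package: gcsim
Title: Structural Similarity of Molecules via Graphs of Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents a molecule by the interconnection pattern of its
    elementary cycles rather than atom-by-atom.  Computes a minimum cycle
    basis with Horton's algorithm on every 2-connected component of the
    hydrogen-suppressed molecular graph, closes it into a canonical
    hierarchical generator, and builds the graph of cycles: vertices are
    generator cycles labelled by length, edges record whether two cycles
    share atoms or are joined by an isthmus chain.  Structural similarity
    of two molecules is the maximum common edge subgraph (MCES) of their
    graphs of cycles, solved exactly as a maximum clique on the
    compatibility product of line graphs, with molecular-graph MCES and
    fragment-set Tanimoto similarity as baselines, plus tools to threshold
    all-pairs similarity matrices into connected components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    ChemmineR,
    stats,
    utils,
    graphics
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
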
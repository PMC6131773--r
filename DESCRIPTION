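Package: supernoder
Title: Recursive Supernode Extraction from Labeled Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers over-represented labeled k-node motifs in a network,
    selects a maximal set of pairwise node-disjoint motif instances with one
    of five heuristics over the instance overlap graph, collapses each
    selected instance into a supernode, and recurses, producing progressively
    simplified networks. Includes exhaustive and sampled connected-subgraph
    enumeration, a label/degree signature census with an explicit
    label-preserving isomorphism check, label-hierarchy remapping, a planted
    motif synthetic-network generator, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble,
    withr
Suggests:
    igraph,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
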
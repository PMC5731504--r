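Package: ComplexSampler
Title: Annealed Sampling of Overlapping Protein Complexes from Weighted
    PPI Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts possibly-overlapping protein complexes from a
    weighted protein-protein interaction network by simulated annealing
    over sets of clusters. A Metropolis-Hastings chain with four
    cluster-editing moves and a Gaussian update of a power-law scaling
    exponent minimizes a regularized score combining a generalized
    density reward with penalties on cluster overlap, on the deviation
    of the cluster-size histogram from a truncated power law, and on
    the total number of clustered proteins. Includes the size-stratified
    precision/recall/F evaluation measure for matching predictions
    against a complex catalogue, catalogue overlap statistics, and a
    synthetic planted-complex benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
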
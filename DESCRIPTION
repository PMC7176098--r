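Package: tmskit
Title: Topology, Repeat and Distant-Homology Analysis of Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting distant homology between families of
    alpha-helical membrane proteins. Provides hydropathy profiling and
    transmembrane-segment (TMS) prediction, Smith-Waterman local alignment
    with shuffle-calibrated E-values, detection of internal TMS repeat
    units (bundle-vs-bundle alignment), transitive homology inference
    between protein families with domain projection and overlap checks,
    confidence scoring with network export, and hierarchical clustering of
    proteins from bit-score distance matrices. Includes a synthetic family
    generator that plants TMS topologies and evolutionary events
    (intragenic duplication, TMS loss and gain, divergence) to serve as
    ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    cluster,
    graphics,
    grDevices,
    igraph,
    methods,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
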
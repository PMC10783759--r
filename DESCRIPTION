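Package: subfam
Title: Automated Monophyletic Subfamily Detection in Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Partitions a rooted phylogenetic tree into monophyletic
    subfamily clusters without user-chosen distance thresholds. The tree's
    patristic distance matrix is embedded in a low-dimensional space (UMAP,
    with a classical multidimensional-scaling bypass for very small trees),
    Gaussian mixture models of increasing component count are fitted and
    scored by the Bayesian Information Criterion, and the selected hard
    clustering is mapped back onto the tree, where any non-monophyletic
    cluster is recursively decomposed into its maximal contained clades.
    Each final cluster is scored by the log ratio of its mean pairwise
    patristic distance to its subtending branch length, and cluster/
    annotation concordance can be quantified with a Fitch parsimony
    randomization test. Includes a planted-partition tree simulator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    mclust,
    uwot,
    phangorn,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph,
    cluster,
    optparse
Config/testthat/edition: 3
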
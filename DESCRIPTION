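Package: finet
Title: Fisher Information Networks for Case Similarity Mapping
Version: 0.1.0
Authors@R:
    person("finet", "maintainers", email = "finet-maintainers@example.org",
           role = c("aut", "cre"))
Description: Builds Fisher Information Networks (FIN) from any probabilistic
    classifier: the class posteriors p(c|x) induce a Riemannian metric over
    feature space (the data-space Fisher information matrix), local distances
    are integrated along straight-line segments, global geodesic distances are
    approximated by all-pairs shortest paths over a nearest-neighbour graph,
    and cases are embedded into a low-dimensional latent space by classical
    multidimensional scaling. Unseen cases are projected into the fixed
    embedding from their Fisher distances to the training cases, supporting
    'patient-like-me' neighbour retrieval. Includes a synthetic Gaussian
    mixture feature generator, PCA preprocessing with variance-retention
    selection, and a one-hidden-layer softmax multilayer perceptron with
    analytic input gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
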
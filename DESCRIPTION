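Package: pondscape
Title: Ensemble Niche Models and Graph-Based Landscape Connectivity for
    Pond-Breeding Amphibians
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Links ensemble ecological-niche modelling to graph-theoretic
    landscape connectivity for pond-breeding amphibians such as Triturus
    newts. Climate-only and land-cover-only suitability ensembles (pluggable
    learners, pseudo-absence sampling, TSS/AUC evaluation, MESS extrapolation
    detection) are multiplied into a habitat suitability index, binarized at
    the 10th percentile of training presences, and turned into a landscape
    graph whose nodes are habitat patches and whose edges are least-cost
    distances over an exponential resistance surface. The interaction-flux
    connectivity metric is computed per patch, interpolated across the
    landscape, z-normalized, combined across species, and compared between
    current and future climate scenarios. A synthetic-landscape generator
    with known true suitability supports end-to-end testing and parameter
    recovery without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
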
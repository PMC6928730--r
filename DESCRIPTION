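Package: cavity2vec
Title: Distributed Vector Representations of Protein Cavity Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein transport pathways (tunnels and cavities) as
    sentences of canonical lining-atom-quadruple node identifiers, learns
    distributed node representations with a from-scratch skip-gram model
    (exact-softmax and negative-sampling regimes), averages node vectors into
    cavity-level embeddings, and analyses cavity dynamics through cosine
    similarity queries, average-link hierarchical and k-means clustering,
    t-SNE projections, length-width (bottleneck) profiles and amino-acid
    composition profiles. Includes a synthetic trajectory generator with
    known ground-truth channel patterns so the whole pipeline is testable
    without external molecular-dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
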
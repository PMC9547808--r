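Package: rwrnet
Title: Random-Walk-with-Restart Prioritization on Multi-Layer Biomedical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multi-layer heterogeneous networks of typed biomedical
    entities (genes, diseases, pathways, phenotypes, chemicals) from edge-list
    and GMT files, couples the layers through shared entities, assembles a
    block transition matrix with per-layer-pair jumping probabilities, runs
    random-walk-with-restart propagation from seed entities, and emits ranked
    candidate tables with percentile ranks per entity type. Includes a
    synthetic-network generator with a planted cross-layer partner so the full
    prioritization pipeline can be benchmarked without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
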
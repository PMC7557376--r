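Package: ddsn
Title: Target-Based Drug-Drug Similarity Networks for Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds weighted drug-drug similarity networks (DDSN) from typed
    drug-target interaction tables: two drugs are linked with a weight equal
    to the number of targets on which they act the same way (both agonist or
    both antagonist). Provides weighted-modularity community detection by
    spectral recursive bisection, an energy-model force-directed layout with
    a layout/modularity agreement check, degree, weighted-degree,
    betweenness and betweenness/degree centralities with power-law tail
    fitting, per-community top-t betweenness/degree prioritization of drug
    repurposing hints with annotation-based confirmation bookkeeping,
    molecular-docking work-order construction, and a synthetic generator of
    typed bipartite interaction data with planted community structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
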
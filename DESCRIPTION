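Package: circnet
Title: Multilevel Circulation-Network Analysis of Food Sampling-Inspection Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed, weighted circulation networks of substandard food
    flows between administrative units (provinces, cities) from tabular
    sampling-inspection records. Provides record cleaning and deduplication,
    offline gazetteer geocoding of free-text manufacturer and distributor
    addresses, network descriptive statistics (degree, weighted degree, in/out
    flow ratio, density, diameter), circulation-intensity scoring with
    Fisher-Jenks natural-breaks classification and pattern quadrants, exact
    node and edge betweenness centrality, Louvain community detection with the
    fast modularity-gain update, Borgatti key-player identification by
    distance-weighted reach, a fully seeded synthetic-data generator with
    ground-truth bookkeeping, and a single pipeline entry point that emits the
    standard report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    readxl,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
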
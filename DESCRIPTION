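Package: supplynet
Title: Directed Network Analysis of Medicine Supply Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building directed buyer-to-supplier networks from
    survey-style outlet and purchasing tables and analysing their structure:
    adjacency-matrix views, trace-based loop counts, empirical degree
    distributions with power-law, exponential and log-normal curve fits
    compared by chi-squared goodness of fit, PageRank centrality with
    explicit dangling-node handling, directed (Fagiolo) and undirected local
    clustering coefficients, bespoke retailer-to-top-level supply-chain
    length statistics, regional and price-category sub-network extraction,
    and a layered preferential-attachment generator that reproduces the
    structural signature of surveyed pharmaceutical supply chains
    (power-law in-degree, log-normal out-degree, no directed cycles beyond
    self-loops, short chains, a dominant geographic hub).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    minpack.lm,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
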
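Package: honcausal
Title: Higher-Order Causation Networks from Accident Causal Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds higher-order causation networks from coded accident causal
    chains. Extracts first- and higher-order path dependencies from ordered
    sequences of causal-factor codes using conditional transfer probabilities
    and a Kullback-Leibler divergence test against a dynamic threshold, wires
    the validated dependencies into a directed higher-order network with
    context-carrying nodes, and computes the standard topological diagnostics
    (degree distribution and its power-law fit, average path length and
    diameter with a seeded random-graph baseline, clustering coefficient,
    betweenness centrality, k-core decomposition). Includes a seeded synthetic
    chain generator with planted higher-order dependencies for validation, and
    exporters for Pajek, CSV and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
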
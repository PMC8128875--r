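Package: misinfonet
Title: Temporal Similarity Networks and Dynamics of Misinformation Streams
Version: 0.1.0
Authors@R:
    person("Misinfonet", "Developers", email = "maintainer@misinfonet.org",
           role = c("aut", "cre"))
Description: Tools for analysing the network dynamics of timestamped
    misinformation streams. Provides a synthetic stream generator with
    topic-cluster structure and ground truth; heavy-tailed popularity model
    selection (power-law versus log-normal maximum likelihood with
    Kolmogorov-Smirnov x_min scanning, semi-parametric bootstrap
    goodness-of-fit, and Vuong-type likelihood-ratio comparison); three
    temporal similarity-network formulations (daily networks, cumulative
    growth, and cumulative growth with a consecutive-day node-deletion rule);
    degree, closeness, betweenness and exact second-order (random-walk
    return-time) centralities with daily-mean series; preferential-attachment
    kernel and node-fitness (growth-exponent) estimation; survivor sets,
    shrink-expand cycle detection and TF-IDF topic-shift summaries; and an
    embedding-based multilayer-perceptron predictor of future central nodes
    with rolling evaluation. A pipeline driver and command-line interface
    orchestrate end-to-end reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
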
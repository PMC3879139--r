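Package: kpairwise
Title: Maximum Entropy Models of Binary Neural Population Activity
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers independent, pairwise (Ising) and K-pairwise maximum
    entropy models from binned binary spike rasters, estimates their
    entropy and partition function by three independent routes
    (heat-capacity temperature integration, Wang-Landau density of
    states, and the silence-probability trick), characterizes the
    model energy landscape (metastable states, basins of attraction,
    transition barriers), and validates model predictions against
    data: population synchrony, triplet correlations, the effective
    field curve, PSTH prediction from the rest of the network, and
    coincidence probabilities. Includes a synthetic-data module that
    emulates the statistical structure of dense retinal multi-electrode
    recordings so that the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
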
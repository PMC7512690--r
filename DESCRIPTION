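Package: phimip
Title: Integrated Information and Minimum Information Partition Search for
    Gaussian Dynamical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three Gaussian measures of integrated information
    (mutual-information based, stochastic interaction, and geometric
    integrated information) for multivariate autoregressive and empirical
    time-series models, and searches for the Minimum Information Partition
    (MIP) -- the bipartition across which integrated information is
    smallest.  Search methods include exhaustive enumeration, Queyranne's
    pendant-pair algorithm for symmetric submodular minimization applied
    as a heuristic to the non-submodular measures, and a replica-exchange
    Markov chain Monte Carlo minimizer.  Includes random-network
    simulation benchmarks with correct-rate, rank, error-ratio and
    partition-correlation accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
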
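Package: hiermod
Title: Correlation-Based Tests for Hierarchical Functional Modularity
    with Latent Binary Interface Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical testing of hierarchical (flat or nested) functional
    modularizations of biological networks from samples of observable
    components alone, without access to the latent interface variables that
    separate modules from the rest of the network.  Implements moment-ratio
    estimators with signal-to-noise cutoffs, delta-method covariances with
    finite-sample correction factors, a gamma-distributed test statistic with
    eigenvalue-based conservativeness scaling, exhaustive enumeration of
    candidate modularizations, a probabilistic Boolean network simulator of
    spiking neural populations with exact enumeration oracles and
    covariance-matched linear surrogate data, and a re-ranking pipeline for
    predicted transcription-factor/target-gene interactions with
    precision-recall evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
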
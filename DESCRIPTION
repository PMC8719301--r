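Package: debcsim
Title: Spiking Cerebello-Cortical Simulation of Delay Eyeblink Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates delay eyeblink conditioning (DEBC) in a spiking
    cerebello-cortical network of leaky integrate-and-fire neurons with
    exponential postsynaptic currents. Two parallel granule-Purkinje-dentate
    pathways drive primary motor and medial prefrontal cortex; conditioned
    responses are acquired through eligibility-kernel long-term depression at
    the parallel-fibre to Purkinje-cell synapses and coincidence-based
    potentiation of the prefrontal-motor projection. Includes the autism
    spectrum disorder manipulations (reduced Purkinje-cell count and
    cerebello-cortical hyper-connectivity via halved transmission delays),
    the full two-group training protocol, conditioned-response rate and
    peak-latency read-outs, and per-session nonparametric group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
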
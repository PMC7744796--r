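Package: prolineswitch
Title: Kinetic Modelling of Prolyl-Isomerization-Gated Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Continuous-time Markov models for ligand-gated ion channel
    gating with a slow prolyl cis/trans isomerization degree of freedom,
    as found in the cyclic nucleotide-modulated channel SthK.  Provides
    deterministic eigen-relaxation and Gillespie single-channel
    simulation of concentration-jump protocols, builders for the
    modulatory, on/off-switch and trans-only (P300A-like) gating
    schemes, mixture-affinity and isomerization free-energy algebra,
    the stopped-flow thallium-flux fitting suite (stretched-exponential
    quench, double-exponential activation, Hill dose-response,
    four-parameter logistic inhibition, catalytic efficiency), and
    seed-deterministic synthetic data generators that emulate the
    stopped-flow assay end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
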
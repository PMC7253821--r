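Package: spikevar
Title: Simulation and Trial-to-Trial Variability Analysis of Poisson Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates cortical spiking during a reaching-style task as pure
    or noise-contaminated (doubly stochastic) Poisson processes, estimates
    trial-wise firing rates by Gaussian-kernel spike density functions (SDF),
    and quantifies trial-to-trial variability with a time-resolved,
    regularized normalized variance (NV) statistic and a count-window Fano
    factor oracle. Includes deterministic fixture generation, plain-text
    serialization of trial sets, rate-level NV binning, pooling across
    simulated units, and a command-line workflow (simulate, analyze, report).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
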
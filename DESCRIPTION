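Package: oulandscape
Title: Multi-Optimum Ornstein-Uhlenbeck Models of Body Mass Evolution on
    Chronograms with Fossil Tips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs macroevolutionary adaptive landscapes for
    continuous traits (primate body mass in particular) by fitting
    Hansen-type multi-optimum Ornstein-Uhlenbeck models to species data on
    time-calibrated phylogenies that may include non-contemporaneous
    (fossil) tips.  Provides exact maximum-likelihood fitting for a fixed
    regime painting, AICc model comparison against Brownian motion and
    single-peak alternatives, a stepwise forward/backward regime search
    that detects convergent regimes, fossil-tip grafting with ghost
    lineages, dataset-variant filters, and simulators for multi-regime OU
    and Brownian traits so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
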
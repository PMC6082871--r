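Package: forcequench
Title: Simulation and Analysis of Force-Clamp Disulfide Cleavage and Reformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for single-molecule force-clamp spectroscopy of
    thiol-mediated SN2 disulfide-bond chemistry in polyproteins. Provides a
    seeded stochastic simulator of extension-vs-time staircases under
    constant-force protocols (two-pulse cleavage kinetics and five-pulse
    reformation assays), change-point step detection with trace-acceptance
    filters, summed-trace reduction kinetics with bootstrap errors,
    Bell/Arrhenius reconstruction of the one-dimensional free-energy
    landscape (distance to the transition state, zero-force rate, barrier
    height), Henderson-Hasselbalch titration fitting for sulfur pKa, and a
    thermodynamic model linking disulfide reformation probability to the
    reaction free energy and nucleophile pKa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
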
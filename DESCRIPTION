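Package: aquametal
Title: Heavy-Metal Pollution Indices and Probabilistic Health Risk for Surface Water
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Assessment pipeline for heavy-metal(loid) contamination of surface
    water. Computes the heavy-metal pollution index (HPI), metal index (MI) and
    Hakanson potential ecological risk index (RI) from monitoring data; the
    USEPA deterministic human-health risk chain (chronic daily intake, hazard
    quotient, hazard index and carcinogenic risk for oral and dermal pathways,
    adult and child receptors); Monte Carlo uncertainty propagation with
    rank-correlation sensitivity analysis; and Spearman correlation with
    hierarchical clustering for source screening. Ships a seeded synthetic
    monitoring-data generator with lognormal marginals and a Gaussian copula,
    calibrated to seasonal per-site means from a seven-station Danube River
    campaign, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
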
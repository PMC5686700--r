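Package: gnrhsense
Title: Information Transfer in GnRH Receptor Signaling to NFAT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much information single cells obtain about
    pulsatile gonadotropin-releasing hormone (GnRH) concentration from their
    NFAT translocation responses. Implements Bayesian (NSB) entropy and
    mutual-information estimation on binned single-cell measurements
    (marginal, joint, trajectory, conditional and second-pulse additional
    information), a deterministic GnRH receptor to Ca2+/calmodulin/
    calcineurin/NFAT translocation model driven by arbitrary pulse
    protocols, a hybrid stochastic layer in which total GnRHR and calmodulin
    levels fluctuate as exponentiated Ornstein-Uhlenbeck processes with a
    controllable fluctuation lifetime, synthetic single-cell cohort
    generators, and an MCMC nucleus-matching cell tracker.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
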
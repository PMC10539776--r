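Package: cidnpr
Title: Magnetic Field Dependence of CIDNP in Flexible Biradicals, NMRD
    Fitting, and Shuttle-Transfer Relaxation Correction
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing chemically induced dynamic nuclear
    polarization (CIDNP) generated in short-lived flexible biradicals,
    built around a distance-resolved stochastic Liouville model of the
    radical-pair mechanism with an exponentially distance-dependent
    exchange interaction, diffusion over an inter-radical distance
    distribution, electron spin relaxation and spin-selective
    recombination. Also provides fitting of nuclear magnetic relaxation
    dispersion (NMRD) curves with a Lorentzian dispersion model,
    reconstruction of true CIDNP field dependences from data attenuated by
    nuclear relaxation during mechanical sample shuttling, a least-squares
    statistic to rank candidate inter-radical distance distributions
    against an observed field dependence, and a synthetic-data generator
    emulating the fast-field-cycling experiment for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
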
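Package: quinbridge
Title: Descriptor and Trajectory Analysis of Twin Intramolecular Hydrogen
    Bridges in Quinonoid Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising substituent effects in
    1,4-naphthoquinone-type compounds carrying one or two intramolecular
    O-H...O hydrogen bridges. Computes the Harmonic Oscillator Model of
    Aromaticity (HOMA) index from bond-length tables or Cartesian
    geometries, the charge of the Substituent Active Region (cSAR)
    descriptor from per-atom partial charges, and barrier/second-minimum
    energetics of one-dimensional proton-transfer scan profiles. For
    molecular-dynamics trajectories it extracts donor-proton and
    proton-acceptor distance series, proton-possession statistics,
    discrete proton-transfer events, inter-bridge synchrony, and atomic
    velocity power spectra with band barycenters. A stochastic
    coupled-bridge trajectory generator with analytically known ground
    truth supports end-to-end validation without external simulation
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
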
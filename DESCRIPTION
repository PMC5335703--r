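Package: acrtools
Title: Quantitative Workflow for Natural Anion Channelrhodopsins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterising natural anion
    channelrhodopsins (ACRs), the light-gated chloride channels of
    cryptophyte algae used as inhibitory optogenetic tools. The package
    couples closed-form electrochemistry (Nernst and
    Goldman-Hodgkin-Katz equations, Henderson liquid-junction
    potentials, visual-pigment spectral templates) with a seeded
    synthetic-photocurrent generator (three-state gating model,
    current-voltage families, action-spectrum scans, leaky
    integrate-and-fire neuron inhibition), the analysis pipeline that
    extracts peak/stationary currents, inactivation, reversal-potential
    shifts, permeability ratios, decay kinetics, action spectra and
    spike-suppression metrics from such recordings, and a
    sequence-analysis layer for selectivity-filter fingerprinting in
    channelrhodopsin-2 reference numbering with profile-based recursive
    homology search. A replica of the study catalog of 22 ACR homologs
    is included.
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
    purrr,
    rlang,
    readr,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    minpack.lm,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
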
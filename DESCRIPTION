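Package: aquapecd
Title: Photoelectron Circular Dichroism Analysis for Aqueous-Phase Chiral
    Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and analysis of liquid-jet C 1s photoelectron
    circular dichroism (PECD) measurements of chiral solutes, with aqueous
    alanine in its three charge states as the reference system. Implements the
    photoelectron angular distribution algebra (Legendre expansion, asymmetry
    factor, magic-angle geometry, analyzer acceptance-angle correction),
    Henderson-Hasselbalch speciation, a synthetic-spectrum generator with
    exponentially modified Gaussian (EMG) peaks atop an inelastic-scattering
    background with Poisson counting noise, the spectrum-conditioning chain
    (polarization-pair baseline normalization, background subtraction,
    constrained multi-peak EMG fitting), and extraction of the dichroic
    parameter b1 per carbon site with error propagation, 250 meV kinetic-energy
    binning, and enantiomer-consistency validation.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
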
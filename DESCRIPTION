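Package: mefopt
Title: Genetic-Algorithm Design of Fluorophore-Conjugated Metal Nanostructures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design tool for metal-enhanced fluorescence (MEF) contrast
    agents. Models the photophysics of a fluorophore coupled to a gold or
    silver ellipsoidal nanostructure (FRET-type quenching rate with spectral
    overlap integral, radiative enhancement rate, differential enhancement
    factor, transfer efficiencies, and a two-branch fluorescence lifetime)
    and optimizes the conjugate geometry (separation distance and dipole
    orientation angles) with a real-parameter genetic algorithm. Nanoparticle
    absorption and scattering cross-sections are generated analytically from
    quasi-static Gans theory for prolate spheroids, or supplied as CSV
    spectra. Includes a post-optimization distance scan, bundled dye and
    nanostructure presets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
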
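Package: xbmech
Title: Multi-Spring Myosin Cross-Bridge Mechanics and Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanochemical models of the myosin cross-bridge built from
    linearly elastic torsional and extensional springs: a four-spring model
    (4sXB) following the S2/lever-arm architecture of myosin II, a two-spring
    reduction (2sXB), and the classic single-spring reference (1sXB). The
    package solves the spring geometry for any head position (analytically for
    the 2sXB, by energy minimisation of the converter point for the 4sXB),
    converts between the internal surface-to-surface filament spacing and the
    d10 lattice spacing of x-ray diffraction, computes state-dependent free
    energies and axial/radial reaction forces, evaluates strain-dependent
    three-state cycling kinetics (Boltzmann-diffusion Monte-Carlo attachment,
    energy-difference power-stroke and detachment rates, detailed-balance
    reverse rates), runs time-stepped single cross-bridge simulations, and
    scans energy/rate/force landscapes over axial offset and lattice spacing,
    including step-size analysis. A command-line interface regenerates the
    landscape datasets as CSV/JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
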
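Package: radkin
Title: Antiradical Kinetics from Solution Thermochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes pH-dependent overall rate coefficients for radical
    scavenging by polyprotic phenolic antioxidants from tabulated solution
    thermochemistry. Covers isodesmic pKa calculation and acid-base
    speciation, exergonicity screening of formal-hydrogen-transfer (FHT)
    and single-electron-transfer (SET) reaction channels, conventional
    transition-state-theory rate constants with Eckart or Wigner tunneling
    corrections, Marcus-theory barriers for electron transfer,
    Collins-Kimball diffusion-corrected apparent rate constants, and the
    fraction-weighted aggregation into per-species totals, overall rate
    coefficients and branching ratios. Includes a synthetic-fixture
    generator producing internally consistent model antioxidant systems
    with known ground-truth kinetics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
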
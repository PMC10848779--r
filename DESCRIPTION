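Package: photorepair
Title: Photokinetics of Cyclobutane Pyrimidine Dimer Self-Repair in DNA Oligonucleotides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward and inverse photokinetic analysis of UV-driven
    self-repair of cyclobutane pyrimidine dimers (CPDs) in short DNA
    oligonucleotides. Provides wavelength-resolved absorbed-photon-dose
    bookkeeping under Beer-Lambert competitive absorption, a reversible
    damaged/repaired photoreaction model with photostationary-state
    analysis, quantum-yield extraction from the initial slope of
    dose-response data, HPLC-style chromatogram synthesis and
    quantification, glycosidic-torsion and base-stacking-overlap geometry
    operators for nucleotide structures, and validated excited-state
    energy-ladder datasets for the sequential electron transfer mechanism.
    A seed-reproducible synthetic-data generator emulates the irradiation
    experiments so every analysis stage can be tested by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    bio3d,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse,
    knitr
Config/testthat/edition: 3
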
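Package: cytodiff
Title: Intracellular Diffusion, Electrostatic Binding and Proteome Charge
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying protein mobility in the bacterial and
    archaeal cytoplasm from fluorescence-recovery-after-photobleaching
    (FRAP) line profiles. Fits a numerical one-dimensional diffusion model
    with reflecting boundaries to recovery stacks, converts effective
    diffusion coefficients into bound fractions and dissociation constants
    through a fast-exchange two-state model of probe-ribosome association,
    fits an ionic-strength-dependent (Debye-Hueckel type) electrostatic
    binding model, and computes sequence-based protein net charge and
    isoelectric points for proteome-wide distributions. Includes
    seed-reproducible generators for synthetic FRAP stacks, two-state
    switching random walks and stand-in proteomes so the whole pipeline is
    testable without microscope data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
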
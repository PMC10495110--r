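Package: dcvflux
Title: Quantification of Dense Core Vesicle Secretion, Golgi Flux and
    Axonal Transport from Fluorescence Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for live-cell imaging assays of the neuronal
    regulated secretory pathway. Detects single dense-core-vesicle (DCV)
    fusion events in NPY-pHluorin time-lapse recordings by F/F0
    thresholding with a rise-time criterion, quantifies the intracellular
    vesicle pool revealed by NH4Cl dequenching with an overlap correction,
    and computes released fractions. Fits first-order export kinetics to
    RUSH (Retention Using Selective Hooks) Golgi-flux traces after
    phase-correlation drift registration, builds kymographs along neurite
    paths and traces particle trajectories to classify anterograde and
    retrograde transport. Includes nested ("SuperPlot") replicate
    statistics, 2^-ddCt qRT-PCR fold changes, electron-microscopy
    morphometry derivations, and a synthetic-movie generator with known
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
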
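Package: cortexflow
Title: Quantifying Flow-Driven Actin Alignment in the Cell Cortex with
    Active Nematic Gel Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how compressive cortical actomyosin flow
    aligns actin filaments into a contractile ring, as in the C. elegans
    zygote. Provides synthetic filament-network image generation with
    controllable orientation bias, nematic order quantification from
    windowed Fourier orientation spectra, particle image velocimetry and
    compression-rate profiling, steady-state and dynamic solvers for a
    one-dimensional active nematic gel model with least-squares fitting of
    the material parameters (relaxation time, flow-alignment coupling,
    alignment length, myosin-coupled active alignment) with bootstrap
    uncertainty and identifiability scans, spatiotemporal cross-correlation
    with distance-to-delay conversion, and prediction of furrow ingression
    from anisotropic active tension.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite,
    pracma,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
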
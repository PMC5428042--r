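Package: polarMSI
Title: Polarimetry-Guided Mass Spectrometry Imaging: Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for polarimetry-guided targeted mass spectrometry of
    tissue. Reconstructs per-pixel Mueller matrices from polarization-resolved
    image stacks, derives depolarization and surviving-polarization maps via
    the Lu-Chipman polar decomposition, co-registers the optical frame with a
    mass-spectrometry stage coordinate system, proposes targeted regions of
    interest from depolarization contrast, simulates DESI-MS raster images and
    PIRL point-sampling spectra over synthetic tissue phantoms, quantifies
    polarimetry-MS concordance, and classifies point-sampling spectra with a
    preprocessing chain (peak alignment, missing-value filtering, PPCA
    imputation, IQR filtering, sum normalization, Pareto scaling) followed by
    PLS-DA.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    MASS,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
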
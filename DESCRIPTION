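Package: osteospectra
Title: Vibrational Spectroscopy of Bone for Chronological Age Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and chemometric analysis of FTIR and Raman
    microspectroscopy of cranial bone for chronological age estimation.
    Provides a synthetic-cohort spectrum generator with age-dependent
    mineral and collagen band composition, the standard preprocessing
    chains for FTIR focal-plane-array images (polynomial baseline
    correction, quality filtering, fingerprint cropping, standard normal
    variate) and Raman point spectra (Savitzky-Golay smoothing, SNV,
    cosmic-spike removal, iterative baseline subtraction), computation of
    the four classical bone-quality outcomes per modality
    (mineral-to-matrix, carbonate-to-phosphate, crystallinity, collagen
    maturity), group statistics with parametric/nonparametric fallback,
    principal component analysis, and NIPALS partial least squares
    regression with venetian-blind cross-validation, Kennard-Stone sample
    partitioning, VIP scores, and genetic-algorithm variable selection
    (GA-PLS).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
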
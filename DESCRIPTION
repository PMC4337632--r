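Package: erkwave
Title: Quantification of Intercellular ERK Activation Waves in Epidermis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify radially propagating bursts of ERK activation
    (SPREADs) and wound-edge ERK activation waves in ratiometric FRET
    time-lapse imaging of epidermis. Provides per-cell flat-versus-sine-sum
    pulse classification, SPREAD origin optimisation, propagation velocity
    and radius estimation, wound-edge distance analyses, spatio-temporal
    association of cell division with SPREAD areas, a Monte Carlo test of
    complete spatial randomness for SPREAD origins, Fucci cell-cycle
    classification, and a synthetic-data generator with full ground truth
    for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
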
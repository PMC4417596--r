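Package: marrowmech
Title: Vertebral Bone Marrow Fat Quantification, Trabecular Morphometry and
    Bone Strength Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-vitro analysis chain linking vertebral bone marrow
    adiposity to bone strength. Implements constrained Gaussian peak fitting
    of multi-echo single-voxel MR spectra with T2 correction to obtain the
    proton-density fat fraction (PDFF), phantom-based QCT calibration with
    trabecular morphometry (BV/TV, trabecular number via the mean intercept
    length method, box-counting fractal dimension, cross-sectional areas),
    failure-load extraction from load-displacement curves, and
    bootstrap-validated pairwise linear regression. A synthetic-data module
    generates spectra, trabecular lattice CT volumes with calibration
    phantoms, softening load curves and correlated specimen cohorts with
    known ground truth, so the full pipeline is testable without access to
    cadaveric specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    pracma,
    nortest,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
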
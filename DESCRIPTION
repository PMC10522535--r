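Package: somatoprf
Title: Two-Dimensional Population Receptive Field Mapping of Somatosensory Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise population receptive field (pRF) analysis of
    vibrotactile fMRI experiments on a 4x4 digit-by-phalanx stimulation grid.
    Builds travelling-wave stimulus descriptions for between-digit,
    within-digit and diagonal paradigms; evaluates four pRF model families
    (2D Gaussian, two sets of 1D Gaussian profiles, and an unconstrained
    site-weight model); fits them per voxel by nonlinear least squares with
    grid-search initialisation; runs the reference Fourier travelling-wave
    analysis (coherence, phase, amplitude, Hommel-corrected p-values);
    compares maps via Dice coefficients and AIC preference matrices;
    constructs PCA-summarised, peak-aligned pRF coverage maps; aggregates
    pRF sizes over functional and anatomical regions of interest; and
    simulates complete synthetic sessions with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    RNifti
Config/testthat/edition: 3
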
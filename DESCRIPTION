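Package: srsfa
Title: Compositional Analysis of Hyperspectral Stimulated Raman Scattering Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Pixel-wise L1-regularized (LASSO) spectral unmixing of hyperspectral
    stimulated Raman scattering (SRS) image stacks in the C-H region, with
    GC-MS-augmented reference weighting for fatty-acid production strains.
    Estimates saturated fatty-acid chain length per pixel from the CH2/CH3
    area-under-curve ratio via a linear calibration on pure standards,
    quantifies unsaturation from the ~3000 1/cm marker band, compares
    recovered chain-length distributions to GC-MS ground truth with the
    Jensen-Shannon divergence, and provides single-cell and colony production
    analytics (region quantification, high-producer classification, growth
    rates from cell-length trajectories). A synthetic hyperspectral scene
    generator with full ground truth supports validation without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    glmnet,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
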
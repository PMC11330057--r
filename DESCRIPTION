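Package: swircaries
Title: Interproximal Caries Detection from SWIR and CP-OCT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and measuring interproximal (Class II) caries
    lesions in short-wavelength infrared (SWIR) reflectance and
    transillumination images and in cross-polarization optical coherence
    tomography (CP-OCT) b-scans. Implements contrast-map transforms with a
    fixed detection threshold, contact-adjacent connected-component lesion
    selection, lesion area/contrast/depth metrics, radiographic lesion
    contrast with scale transfer, a cylindrical-ruler depth measurement on
    b-scans with refractive-index correction, and the detection-rate and
    repeated-measures statistics used to compare imaging methods. A synthetic
    phantom generator with known ground truth makes every stage testable
    without clinical images.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    emmeans,
    lme4,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
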
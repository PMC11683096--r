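Package: glymphr
Title: Glymphatic Function Analysis with the DTI-ALPS Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to quantify brain glymphatic function from diffusion
    tensor imaging using the ALPS (analysis along the perivascular space)
    index, and to carry the index through a full clinical readout. Includes
    a synthetic diffusion phantom and cohort generator with closed-form
    ground truth, voxelwise tensor estimation (OLS/WLS) with fractional
    anisotropy and colour-encoded direction maps, automatic periventricular
    ROI placement by colour-channel peak search, the ALPS ratio itself,
    covariate-adjusted group contrasts, partial correlations with
    false-discovery-rate control, bootstrap mediation through grey-matter
    proportion, and prognostic logistic modelling with backward elimination
    and ROC characterisation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
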
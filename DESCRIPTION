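Package: wmbrainage
Title: White Matter Brain Age from Diffusion MRI Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates white matter brain age from five co-registered
    diffusion-tensor maps (FA, MD, AxD, RD, MO) with an eight-block 3D
    convolutional network and a linear fusion head, applies validation-set
    bias correction to obtain the white matter brain age gap (WMBAG), and
    runs the downstream epidemiological analyses: composite vascular risk
    scoring, APOE coding, standardised cognition composites, ANCOVA and
    dummy-coded regression models with sex interactions, bootstrap
    mediation, and two-timepoint longitudinal change analysis. Includes a
    fully synthetic cohort generator (metadata, 3D NIfTI phantom maps,
    cognition with a planted mediation structure, and a longitudinal
    subset) so that every stage of the pipeline can be exercised and
    validated without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
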
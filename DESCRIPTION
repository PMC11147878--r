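Package: replocal
Title: Multivariate Localization of Language-Responsive Cortex by
    Representational Fidelity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Defines multivariate regions of interest (mROI) from
    multi-subject fMRI beta images by leave-one-subject-out
    representational fidelity searchlight mapping, and evaluates
    single-word semantic representation within them using
    partial-correlation representational similarity analysis (RSA) that
    controls for orthographic and phonological stimulus structure.
    Includes feature-weighted phonological and orthographic edit
    distances, spherical searchlight machinery, mask-normalized Gaussian
    smoothing, 3D connected-component labeling and peak extraction,
    sign-flip cluster-extent correction, ROI querying and laterality
    indices, and a synthetic multi-subject data generator with planted
    representational geometry for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
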
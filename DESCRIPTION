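Package: dbsir
Title: Diffusion Basis Spectrum Imaging of Optic Nerve White Matter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-compartment modeling of diffusion-weighted MRI signals
    in coherent white-matter tracts. Implements the diffusion basis
    spectrum imaging (DBSI) forward model (a single anisotropic fiber
    tensor plus a non-negative spectrum of isotropic diffusion
    components), its inversion by regularized non-negative least squares
    with a nested search over fiber diffusivities, a conventional
    diffusion tensor imaging (DTI) comparison fit, a synthetic phantom
    generator for longitudinal sham/injury optic-nerve cohorts with
    Rician noise, and region-of-interest summaries (nerve volume, axon
    volume, percent changes, correlations, two-way ANOVA) for group
    analysis of traumatic optic neuropathy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    car,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
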
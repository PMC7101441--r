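Package: elastopress
Title: Noninvasive Tumour Pressure Estimation from MR Elastography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the total (fluid plus solid) pressure inside a roughly
    spherical, pressurized inclusion from 3D complex-valued MR elastography
    (MRE) wave displacement volumes. A pressurized tumour finitely deforms the
    surrounding tissue, which makes an intrinsically isotropic medium appear
    anisotropic to shear waves and biases standard stiffness reconstructions.
    The package corrects the local wave inversion with fourth-order
    neo-Hookean modification tensors built from an analytic incompressible
    spherical-shell inflation field, sweeps the inflation scaling to minimize
    peritumoural stiffness heterogeneity, and converts the selected scaling to
    an inclusion pressure through a closed-form inflating-sphere model. A
    frequency-domain viscoelastic wave simulator with the same deformation
    physics, uniform additive noise, and Gaussian smoothing generates fully
    synthetic test data at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
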
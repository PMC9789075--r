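Package: AccelT2
Title: Accelerated Quantitative T2 Mapping with ROI-Specific Losses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for simulating and evaluating accelerated multi-echo
    T2 relaxometry acquisitions. Generates synthetic aligned multi-echo
    phantoms with known ground-truth T2, retrospectively undersamples
    k-space with center-weighted variable-density Poisson-disc patterns
    restricted to elliptical ky-kz coverage (with temporally-closest-echo
    line sharing), fits mono-exponential T2 maps by vectorised
    Levenberg-Marquardt, defines a recurrent UNet image-to-map network
    with ROI-weighted multi-component training losses, and scores T2
    fidelity and texture retention with NRMSE, Bland-Altman agreement,
    masked GLCM texture metrics and intraclass correlation coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
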
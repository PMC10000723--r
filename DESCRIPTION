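Package: spinefs
Title: Synthetic Fat-Saturated Spine MRI by Conditional Adversarial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes sagittal T2-weighted fat-saturated spine MR images
    from co-registered T1-weighted and non-fat-saturated T2-weighted inputs
    with a conditional adversarial network (U-Net generator trained on a joint
    structural-similarity plus adversarial loss, patch discriminator), and
    evaluates the diagnostic value of the synthetic contrast with inter-rater
    agreement statistics (Cohen's kappa with confidence intervals, Wilcoxon
    signed-rank on paired kappas, McNemar tests on grading accuracy). A
    multi-compartment spine phantom simulator provides paired multi-contrast
    volumes with graded pathologies and simulated readers, so the full
    pipeline runs and is testable at desk scale without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    RNifti,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
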